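# Default synthetic-cohort parameters: healthy older adults (HOA).
group: HOA
n_participants: 21
passes_per_speed: 10
fs_hz: 200
conditions:
  slow:
    speed_mean: 0.67
    speed_sd: 0.17
    hip_exc_mean: 34.6
    hip_exc_sd: 7.4
    knee_exc_mean: 59.6
    knee_exc_sd: 8.1
    cadence_spm: 96
    steps_per_pass: 5
  preferred:
    speed_mean: 1.07
    speed_sd: 0.21
    hip_exc_mean: 40.5
    hip_exc_sd: 7.6
    knee_exc_mean: 65.2
    knee_exc_sd: 8.6
    cadence_spm: 110
    steps_per_pass: 3
  fast:
    speed_mean: 1.45
    speed_sd: 0.27
    hip_exc_mean: 45.2
    hip_exc_sd: 7.6
    knee_exc_mean: 62.6
    knee_exc_sd: 9.7
    cadence_spm: 124
    steps_per_pass: 3
lag_mean_deg: 55
lag_sd_deg: 8
lag_between_sd_deg: 7
hip_offset_deg: 5
knee_offset_deg: 25
noise:
  accel_sd: 0.05
  gyro_sd: 0.005
  mag_sd: 0.3
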