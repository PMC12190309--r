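# Default synthetic-cohort parameters: people with Parkinson's disease (PD).
# Walking speeds and joint excursions follow published descriptive statistics
# for mild-to-moderate PD walking at slow / preferred / fast speeds; phase-lag
# and cadence values are the package's documented modelling choices.
group: PD
n_participants: 27
passes_per_speed: 10
fs_hz: 200
conditions:
  slow:
    speed_mean: 0.65
    speed_sd: 0.17
    hip_exc_mean: 30.2
    hip_exc_sd: 7.4
    knee_exc_mean: 53.4
    knee_exc_sd: 8.4
    cadence_spm: 96
    steps_per_pass: 5
  preferred:
    speed_mean: 0.97
    speed_sd: 0.18
    hip_exc_mean: 34.5
    hip_exc_sd: 7.3
    knee_exc_mean: 55.3
    knee_exc_sd: 9.2
    cadence_spm: 110
    steps_per_pass: 3
  fast:
    speed_mean: 1.19
    speed_sd: 0.34
    hip_exc_mean: 39.5
    hip_exc_sd: 10.5
    knee_exc_mean: 55.5
    knee_exc_sd: 9.7
    cadence_spm: 124
    steps_per_pass: 3
lag_mean_deg: 60
lag_sd_deg: 10
lag_between_sd_deg: 7
hip_offset_deg: 5
knee_offset_deg: 25
noise:
  accel_sd: 0.05
  gyro_sd: 0.005
  mag_sd: 0.3
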