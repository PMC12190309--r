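# Shared fixtures, all generated in code.

# sinusoid sampled at fs for dur seconds
make_sine <- function(freq_hz, fs = 200, dur_s = 10, amp = 1, phase_rad = 0,
                      offset = 0) {
  t <- seq(0, dur_s, by = 1 / fs)
  offset + amp * sin(2 * pi * freq_hz * t + phase_rad)
}

# uniformly random unit quaternions (Shoemake's method)
random_quats <- function(n) {
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  cbind(sqrt(1 - u1) * sin(2 * pi * u2),
        sqrt(1 - u1) * cos(2 * pi * u2),
        sqrt(u1) * sin(2 * pi * u3),
        sqrt(u1) * cos(2 * pi * u3))
}

# amplitude of the freq_hz component of x (uniform sampling at fs), estimated
# over an integer number of periods in the middle of the signal
tone_amplitude <- function(x, freq_hz, fs) {
  n <- length(x)
  per <- fs / freq_hz
  k <- floor((n * 0.8) / per)
  span <- floor(n * 0.1) + seq_len(round(k * per))
  t <- (span - 1) / fs
  2 * Mod(mean(x[span] * exp(-2i * pi * freq_hz * t)))
}

# balanced toy participant-summary table for the statistics modules
toy_summaries <- function(n_per_group = 6, seed = 42) {
  set.seed(seed)
  tidyr::expand_grid(
    participant = sprintf("P%02d", seq_len(2 * n_per_group)),
    speed_cond = c("slow", "preferred", "fast")
  ) |>
    dplyr::mutate(
      group = ifelse(as.integer(substring(participant, 2)) <= n_per_group,
                     "HOA", "PD"),
      walking_speed_mps = rnorm(dplyr::n(), 1, 0.2),
      marp_deg = rnorm(dplyr::n(), 60, 8),
      dp_deg = rnorm(dplyr::n(), 10, 2),
      hip_excursion_deg = rnorm(dplyr::n(), 38, 6),
      knee_excursion_deg = rnorm(dplyr::n(), 60, 8)
    )
}

# tiny cohort specs for fast end-to-end runs
small_spec <- function(group, n = 6, passes = 2) {
  spec <- default_cohort_spec(group)
  spec$n_participants <- n
  spec$passes_per_speed <- passes
  spec
}
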