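test_that("degenerate lag variance gives exactly the mean lag every cycle", {
  p <- synth_pass(40, 65, lag_mean_deg = 90, lag_sd_deg = 0, n_cycles = 5)
  expect_equal(p$lag_deg, rep(90, 5), tolerance = 1e-12)
})

test_that("per-cycle excursion equals the drawn excursion within 0.1 degree", {
  set.seed(31)
  for (rep in 1:5) {
    hip_exc <- runif(1, 25, 45)
    knee_exc <- runif(1, 50, 70)
    p <- synth_pass(hip_exc, knee_exc, lag_sd_deg = 10, n_cycles = 4,
                    cadence_spm = sample(90:125, 1))
    for (k in seq_len(p$n_cycles)) {
      idx <- p$ic_index[k]:p$ic_index[k + 1]
      expect_lt(abs(diff(range(p$angles$hip_deg[idx])) - hip_exc), 0.1)
      expect_lt(abs(diff(range(p$angles$knee_deg[idx])) - knee_exc), 0.1)
    }
  }
})

test_that("generators are bit-identical under a fixed seed", {
  set.seed(5); p1 <- synth_pass(40, 65, n_cycles = 3)
  set.seed(5); p2 <- synth_pass(40, 65, n_cycles = 3)
  expect_identical(p1, p2)

  c1 <- simulate_cohort(small_spec("hoa", n = 2, passes = 1), seed = 9)
  c2 <- simulate_cohort(small_spec("hoa", n = 2, passes = 1), seed = 9)
  expect_identical(c1$passes$signals, c2$passes$signals)
  expect_identical(c1$participants, c2$participants)
})

test_that("shank gyro has one mid-swing peak per cycle and exact noiseless crossings", {
  p <- synth_pass(40, 65, lag_sd_deg = 0, n_cycles = 3)
  g <- as.numeric(generate_shank_gyro(p))
  # brute-force local-maximum scan above half the peak height; flat-topped
  # peaks (equal neighbouring samples) count once, at their right edge
  n <- length(g)
  i <- 2:(n - 1)
  is_peak <- i[g[i] >= g[i - 1] & g[i] > g[i + 1]]
  big <- is_peak[g[is_peak] > 3]
  in_bout <- big[big >= p$ic_index[1] - 0.5 * p$period_s * p$fs]
  expect_equal(length(in_bout), 3 + 1)  # one per cycle plus the lead-in swing
  expect_equal(length(big), length(in_bout))  # nothing outside the bout

  # noiseless negative-going zero-crossings sit exactly on the true ICs
  cross <- which(g[-length(g)] > 0 & g[-1] <= 0) + 1L
  expect_true(all(p$ic_index %in% cross))
  expect_equal(g[p$ic_index], rep(0, length(p$ic_index)))
})

test_that("doubling cadence halves the inter-IC spacing within one sample", {
  p1 <- synth_pass(40, 65, cadence_spm = 60, n_cycles = 3)
  p2 <- synth_pass(40, 65, cadence_spm = 120, n_cycles = 3)
  d1 <- unique(diff(p1$ic_index))
  d2 <- unique(diff(p2$ic_index))
  expect_lte(abs(d1 - 2 * d2), 1)
})

test_that("cohort draws match the configured moments at n = 200 within 3 SE", {
  spec <- default_cohort_spec("hoa")
  spec$n_participants <- 200
  spec$passes_per_speed <- 1
  coh <- simulate_cohort(spec, seed = 123, noisy = FALSE)
  pref <- dplyr::filter(coh$participants, speed_cond == "preferred")
  cc <- spec$conditions$preferred
  for (fld in list(c("speed_mps", "speed_mean", "speed_sd"),
                   c("hip_excursion_deg", "hip_exc_mean", "hip_exc_sd"),
                   c("knee_excursion_deg", "knee_exc_mean", "knee_exc_sd"))) {
    se <- cc[[fld[3]]] / sqrt(200)
    expect_lt(abs(mean(pref[[fld[1]]]) - cc[[fld[2]]]), 3 * se)
  }
  # per-cycle lag draws: mean near the spec mean; pooled SD combines the
  # trial-to-trial and between-participant components
  pooled_sd <- sqrt(spec$lag_sd_deg^2 + spec$lag_between_sd_deg^2)
  expect_lt(abs(mean(coh$lags$lag_deg) - spec$lag_mean_deg),
            3 * pooled_sd / sqrt(200))  # ~200 independent participants
  expect_lt(abs(sd(coh$lags$lag_deg) - pooled_sd), 1)
  # within a participant the cycle-to-cycle spread is the trial SD
  within_sd <- coh$lags |>
    dplyr::group_by(participant) |>
    dplyr::summarise(s = sd(lag_deg)) |>
    dplyr::pull(s) |>
    mean()
  expect_lt(abs(within_sd - spec$lag_sd_deg), 1)
})

test_that("truth tables agree with emitted signal lengths and events", {
  coh <- simulate_cohort(small_spec("pd", n = 2, passes = 2), seed = 3)
  for (i in seq_len(nrow(coh$passes))) {
    row <- coh$passes[i, ]
    ev <- dplyr::filter(coh$events, participant == row$participant,
                        speed_cond == row$speed_cond, pass == row$pass)
    expect_true(all(diff(ev$ic_index) > 0))
    expect_lte(max(ev$ic_index), nrow(row$signals[[1]]))
    lg <- dplyr::filter(coh$lags, participant == row$participant,
                        speed_cond == row$speed_cond, pass == row$pass)
    expect_equal(nrow(lg), nrow(ev) - 1)  # one lag per cycle
  }
})

test_that("static raw emission reads gravity and zero rate; ranges clip with warning", {
  # static pass: tiny excursion so the segment barely moves
  p <- synth_pass(0.01, 0.01, lag_sd_deg = 0, n_cycles = 2)
  imu <- generate_raw_imu(p)
  expect_equal(mean(sqrt(imu$pelvis$ax^2 + imu$pelvis$ay^2 + imu$pelvis$az^2)),
               9.80665, tolerance = 1e-9)
  expect_lt(max(abs(imu$pelvis$gx), abs(imu$pelvis$gy), abs(imu$pelvis$gz)), 1e-9)

  set.seed(33)
  pbig <- synth_pass(40, 65, n_cycles = 2)
  w <- testthat::capture_warnings(
    generate_raw_imu(pbig, noise = list(accel_sd = 200, gyro_sd = 0, mag_sd = 0)))
  expect_true(any(grepl("clipping", w)))
})

test_that("raw IMU emission is seed-reproducible", {
  p <- synth_pass(40, 65, lag_sd_deg = 0, n_cycles = 2)
  set.seed(7)
  a <- generate_raw_imu(p, noise = list(accel_sd = 0.05, gyro_sd = 0.005, mag_sd = 0.3))
  set.seed(7)
  b <- generate_raw_imu(p, noise = list(accel_sd = 0.05, gyro_sd = 0.005, mag_sd = 0.3))
  expect_identical(a, b)
})

test_that("cohort_spec validates its invariants", {
  spec <- default_cohort_spec("pd")
  expect_s3_class(spec, "cohort_spec")
  bad <- spec$conditions
  bad$slow$speed_mean <- -1
  expect_error(cohort_spec("PD", 10, bad), "positive")
  expect_error(cohort_spec("PD", 1, spec$conditions), "at least 2")
  expect_error(synth_pass(-5, 60), "positive")
  expect_error(synth_pass(40, 65, cadence_spm = 0), "cadence")
})
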