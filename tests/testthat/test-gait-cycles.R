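test_that("noiseless synthetic passes are detected exactly, with no extras", {
  set.seed(51)
  for (nc in 3:5) {
    p <- synth_pass(40, 65, n_cycles = nc, cadence_spm = sample(95:120, 1))
    g <- as.numeric(generate_shank_gyro(p))
    ev <- detect_initial_contacts(g, p$fs)
    expect_equal(ev$ic_index, as.integer(p$ic_index))
    expect_true(all(ev$midswing_index < ev$ic_index))
  }
})

test_that("the sign-convention flag recovers events from a flipped signal", {
  p <- synth_pass(40, 65, n_cycles = 3)
  g <- as.numeric(generate_shank_gyro(p))
  ev <- detect_initial_contacts(-g, p$fs, convention = "negative_midswing")
  expect_equal(ev$ic_index, as.integer(p$ic_index))
})

test_that("degenerate signals yield empty events without crashing", {
  expect_warning(ev <- detect_initial_contacts(rep(0, 1000), 200), "no mid-swing")
  expect_equal(nrow(ev), 0)
})

test_that("noisy detection stays within one sample of the truth", {
  set.seed(52)
  for (rep in 1:5) {
    p <- synth_pass(40, 65, n_cycles = 4)
    g <- as.numeric(generate_shank_gyro(p, noise_sd = 0.05))
    gf <- lowpass_filter(g, fs = p$fs)
    ev <- detect_initial_contacts(gf, p$fs)
    expect_equal(length(ev$ic_index), length(p$ic_index))
    expect_lte(max(abs(ev$ic_index - p$ic_index)), 1)
  }
})

test_that("segmentation counts cycles and interpolates exactly on ramps", {
  fs <- 100
  n <- 301
  ang <- tibble::tibble(time_s = (seq_len(n) - 1) / fs,
                        hip_deg = seq(0, 30, length.out = n),
                        knee_deg = seq(10, 40, length.out = n))
  ic <- c(1L, 101L, 201L, 301L)
  cyc <- segment_and_normalize(ang, ic)
  expect_equal(length(unique(cyc$cycle)), 3)  # 4 ICs -> 3 cycles
  # linear input stays linear with exact endpoints
  c1 <- dplyr::filter(cyc, cycle == 1)
  expect_equal(c1$hip_deg, seq(ang$hip_deg[1], ang$hip_deg[101], length.out = 101),
               tolerance = 1e-12)
  expect_equal(c1$hip_deg[1], ang$hip_deg[1])
  expect_equal(c1$hip_deg[101], ang$hip_deg[101])
})

test_that("normalized peak location matches the analytic position", {
  fs <- 200
  n <- 241  # 1.2 s cycle
  t <- (seq_len(n) - 1) / fs
  ang <- tibble::tibble(time_s = t,
                        hip_deg = sin(2 * pi * t / 1.2),
                        knee_deg = sin(2 * pi * t / 1.2))
  cyc <- segment_and_normalize(ang, c(1L, n))
  pk <- cyc$pct[which.max(dplyr::filter(cyc, cycle == 1)$hip_deg)]
  expect_lt(abs(pk - 25), 1)  # sine peaks at 25% of the cycle
})

test_that("duration gate discards implausible cycles", {
  fs <- 200
  n <- 1001
  ang <- tibble::tibble(time_s = (seq_len(n) - 1) / fs,
                        hip_deg = rnorm(n), knee_deg = rnorm(n))
  # cycles of 0.25 s (too short), 1 s (kept), 3 s would exceed the series
  expect_message(cyc <- segment_and_normalize(ang, c(1L, 51L, 251L)),
                 "duration gate")
  expect_equal(length(unique(cyc$cycle)), 1)
  expect_equal(cycle_info(cyc)$duration_s, 1)
})

test_that("fewer than two ICs give an empty cycle set", {
  ang <- tibble::tibble(time_s = (0:99) / 200, hip_deg = rnorm(100),
                        knee_deg = rnorm(100))
  cyc <- segment_and_normalize(ang, integer(0))
  expect_equal(nrow(cyc), 0)
  cyc1 <- segment_and_normalize(ang, 5L)
  expect_equal(nrow(cyc1), 0)
})

test_that("normalization is idempotent on an already-101-point cycle", {
  set.seed(53)
  fs <- 100
  y <- lowpass_filter(rnorm(101), fs = 100, cutoff_hz = 10)
  ang <- tibble::tibble(time_s = (0:100) / fs, hip_deg = y, knee_deg = y)
  cyc <- segment_and_normalize(ang, c(1L, 101L))
  expect_equal(dplyr::filter(cyc, cycle == 1)$hip_deg, y, tolerance = 1e-9)
})

test_that("excursion arithmetic: amplitude, offsets, averaging", {
  # 30-degree amplitude sinusoid over full cycles -> excursion 60
  p <- synth_pass(60, 60, lag_sd_deg = 0, n_cycles = 3)
  cyc <- segment_and_normalize(p$angles, p$ic_index)
  exc <- joint_excursion(cyc)
  expect_equal(exc$mean_excursion_deg[exc$joint == "hip"], 60, tolerance = 0.1)

  # invariant to constant offset
  ang2 <- p$angles
  ang2$hip_deg <- ang2$hip_deg + 123.4
  cyc2 <- segment_and_normalize(ang2, p$ic_index)
  exc2 <- joint_excursion(cyc2)
  expect_equal(exc2$mean_excursion_deg[exc2$joint == "hip"],
               exc$mean_excursion_deg[exc$joint == "hip"], tolerance = 1e-9)

  # constant angle -> zero excursion; mean of {50,60,70} is 60
  const <- tibble::tibble(time_s = (0:400) / 200, hip_deg = rep(7, 401),
                          knee_deg = rep(7, 401))
  ce <- joint_excursion(segment_and_normalize(const, c(1L, 201L, 401L)))
  expect_equal(ce$mean_excursion_deg, c(0, 0))
  info <- tibble::tibble(hip_deg_excursion = c(50, 60, 70))
  expect_equal(joint_excursion(info)$mean_excursion_deg, 60)

  expect_error(joint_excursion(tibble::tibble(hip_deg_excursion = numeric())),
               "undefined")
})
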