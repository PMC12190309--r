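static_rec <- function(q = c(1, 0, 0, 0), n = 400, fs = 200,
                       g_w = c(0, 9.80665, 0), m_w = c(19, -44, 5)) {
  qm <- matrix(q, n, 4, byrow = TRUE)
  qc <- quat_conjugate(qm)
  imu_recording((seq_len(n) - 1) / fs,
                accel = quat_rotate(qc, matrix(g_w, n, 3, byrow = TRUE)),
                gyro = matrix(0, n, 3),
                mag = quat_rotate(qc, matrix(m_w, n, 3, byrow = TRUE)),
                placement = "pelvis")
}

test_that("static noiseless fusion converges to the true attitude", {
  # level sensor
  ors <- complementary_fuse(static_rec())
  eul <- quat_to_euler_zyx(gaitcoord:::orientation_quat(ors))
  expect_lt(max(abs(eul[100:400, ])), 1e-9)

  # tilted sensor: 30 degrees about the medio-lateral axis
  q30 <- quat_from_axis_angle(c(0, 0, 1), pi / 6)
  ors <- complementary_fuse(static_rec(q30))
  eul <- quat_to_euler_zyx(gaitcoord:::orientation_quat(ors))
  expect_lt(max(abs(rad2deg <- eul[100:400, "z"] * 180 / pi - 30)), 1e-6)
})

test_that("constant-rate rotation about the vertical recovers the yaw rate", {
  fs <- 200
  n <- 2 * fs + 1
  t <- (seq_len(n) - 1) / fs
  # world vertical is Y: yaw at 90 deg/s
  q <- quat_from_axis_angle(c(0, 1, 0), pi / 2 * t)
  qc <- quat_conjugate(q)
  g_w <- c(0, 9.80665, 0); m_w <- c(19, -44, 5)
  gyro <- matrix(c(0, pi / 2, 0), n, 3, byrow = TRUE)  # body rate = world rate here
  rec <- imu_recording(t,
                       accel = quat_rotate(qc, matrix(g_w, n, 3, byrow = TRUE)),
                       gyro = gyro,
                       mag = quat_rotate(qc, matrix(m_w, n, 3, byrow = TRUE)),
                       placement = "pelvis")
  ors <- complementary_fuse(rec)
  qf <- gaitcoord:::orientation_quat(ors)
  # heading directly from the quaternion (2 atan2(qy, qw) for a Y rotation):
  # immune to the asin fold of the Euler decomposition past 90 degrees
  yaw <- signal::unwrap(2 * atan2(qf[, 3], qf[, 1])) * 180 / pi
  sel <- t >= 1
  rate <- coef(lm(yaw[sel] ~ t[sel]))[2]
  expect_lt(abs(rate - 90) / 90, 0.01)
})

test_that("gain 0 reduces to pure gyroscope integration", {
  set.seed(41)
  fs <- 200
  n <- 200
  gyro <- matrix(rnorm(3 * n, 0, 1), n, 3)
  rec <- static_rec(n = n)
  rec[c("gx", "gy", "gz")] <- as.data.frame(gyro)
  fused <- complementary_fuse(rec, gain = 0)
  # brute-force quaternion integration oracle from the same initial attitude
  q <- matrix(0, n, 4)
  q[1, ] <- c(1, 0, 0, 0)
  for (k in 2:n) {
    q[k, ] <- quat_multiply(q[k - 1, , drop = FALSE],
                            quat_exp(gyro[k, , drop = FALSE] / fs))
  }
  err <- abs(gaitcoord:::orientation_quat(fused)) - abs(q)
  expect_lt(max(abs(err)), 1e-6)
})

test_that("relative orientation composes and inverts correctly", {
  set.seed(42)
  n <- 100
  t <- (seq_len(n) - 1) / 200
  qa <- random_quats(n)
  qb <- random_quats(n)
  oa <- orientation_series(t, qa)
  ob <- orientation_series(t, qb)

  # self-relative is the identity
  rel_aa <- relative_orientation(oa, oa)
  q_aa <- gaitcoord:::orientation_quat(rel_aa)
  expect_lt(max(abs(abs(q_aa[, 1]) - 1)), 1e-12)

  # proximal identity + 30 degree distal rotation about ML axis
  oi <- orientation_series(t, matrix(c(1, 0, 0, 0), n, 4, byrow = TRUE))
  o30 <- orientation_series(t, matrix(quat_from_axis_angle(c(0, 0, 1), pi / 6),
                                      n, 4, byrow = TRUE))
  rel <- to_euler_zyx(relative_orientation(oi, o30))
  expect_equal(rel$z_deg, rep(30, n), tolerance = 1e-9)

  # algebraic round trip: prox * rel == dist
  rel_ab <- relative_orientation(oa, ob)
  qd <- quat_multiply(gaitcoord:::orientation_quat(oa),
                      gaitcoord:::orientation_quat(rel_ab))
  err <- pmin(apply(abs(qd - gaitcoord:::orientation_quat(ob)), 1, max),
              apply(abs(qd + gaitcoord:::orientation_quat(ob)), 1, max))
  expect_lt(max(err), 1e-12)

  expect_error(relative_orientation(oa, ob[1:50, ]), "length")
})

test_that("joint angles: identical sensors give zero, offsets pass through", {
  n <- 50
  t <- (seq_len(n) - 1) / 200
  q <- matrix(quat_from_axis_angle(c(0, 0, 1), 0.3), n, 4, byrow = TRUE)
  o <- orientation_series(t, q)
  ja <- compute_joint_angles(o, o, o)
  expect_lt(max(abs(ja$hip_deg), abs(ja$knee_deg)), 1e-9)

  # thigh flexed 30 degrees vs pelvis, shank aligned with thigh
  oi <- orientation_series(t, matrix(c(1, 0, 0, 0), n, 4, byrow = TRUE))
  o30 <- orientation_series(t, matrix(quat_from_axis_angle(c(0, 0, 1), pi / 6),
                                      n, 4, byrow = TRUE))
  ja <- compute_joint_angles(oi, o30, o30)
  expect_equal(ja$hip_deg, rep(30, n), tolerance = 1e-9)
  expect_lt(max(abs(ja$knee_deg)), 1e-9)
})

test_that("a common world rotation leaves joint angles unchanged", {
  set.seed(43)
  p <- synth_pass(40, 65, lag_sd_deg = 5, n_cycles = 2)
  imu <- generate_raw_imu(p)
  ors <- lapply(imu, complementary_fuse)
  ja <- compute_joint_angles(ors$pelvis, ors$thigh_r, ors$shank_r)
  qr <- random_quats(1)
  rot <- lapply(ors, function(o) {
    orientation_series(o$time_s,
                       quat_multiply(qr, gaitcoord:::orientation_quat(o)))
  })
  ja2 <- compute_joint_angles(rot$pelvis, rot$thigh_r, rot$shank_r)
  expect_lt(max(abs(ja$hip_deg - ja2$hip_deg)), 1e-6)
  expect_lt(max(abs(ja$knee_deg - ja2$knee_deg)), 1e-6)
})

test_that("zero-noise raw emission round-trips the joint waveforms", {
  set.seed(44)
  p <- synth_pass(40, 65, lag_sd_deg = 10, n_cycles = 3)
  imu <- generate_raw_imu(p)
  ors <- lapply(imu, complementary_fuse)
  ja <- compute_joint_angles(ors$pelvis, ors$thigh_r, ors$shank_r)
  expect_lt(sqrt(mean((ja$hip_deg - p$angles$hip_deg)^2)), 0.5)
  expect_lt(sqrt(mean((ja$knee_deg - p$angles$knee_deg)^2)), 0.5)
})

test_that("fusion norms stay unit and degenerate accel samples are skipped", {
  set.seed(45)
  p <- synth_pass(40, 65, n_cycles = 2)
  imu <- generate_raw_imu(p, noise = list(accel_sd = 0.05, gyro_sd = 0.005,
                                          mag_sd = 0.3))
  rec <- imu$thigh_r
  rec[10, c("ax", "ay", "az")] <- 0  # dead sample
  expect_message(ors <- complementary_fuse(rec), "skipped")
  qn <- sqrt(rowSums(gaitcoord:::orientation_quat(ors)^2))
  expect_lt(max(abs(qn - 1)), 1e-9)
})
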