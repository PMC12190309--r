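#' Orientation series
#'
#' An `orientation_series` is a tibble with one unit quaternion per sample
#' (columns `time_s`, `qw`, `qx`, `qy`, `qz`), scalar-first Hamilton
#' convention, mapping the sensor frame to the world frame. Temporal sign
#' continuity is enforced on construction.
#'
#' @param time_s time vector (s).
#' @param q n x 4 quaternion matrix.
#' @export
orientation_series <- function(time_s, q) {
  q <- quat_normalize(as_quat_matrix(q))
  q <- quat_enforce_continuity(q)
  stopifnot(length(time_s) == nrow(q))
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4])
  class(out) <- c("orientation_series", class(out))
  out
}

orientation_quat <- function(x) {
  as.matrix(x[c("qw", "qx", "qy", "qz")])
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# TRIAD attitude from simultaneous accelerometer and magnetometer readings:
# builds matched orthonormal triads from the measured and reference vector
# pairs. Returns an n x 4 quaternion matrix; rows with a zero-norm reading
# come back as NA (caller decides how to handle them).
triad_orientation <- function(accel, mag, g_ref, m_ref) {
  n <- nrow(accel)
  w1 <- g_ref / sqrt(sum(g_ref^2))
  w2 <- c(g_ref[2] * m_ref[3] - g_ref[3] * m_ref[2],
          g_ref[3] * m_ref[1] - g_ref[1] * m_ref[3],
          g_ref[1] * m_ref[2] - g_ref[2] * m_ref[1])
  if (sqrt(sum(w2^2)) < 1e-9) abort("reference gravity and magnetic field are parallel")
  w2 <- w2 / sqrt(sum(w2^2))
  w3 <- c(w1[2] * w2[3] - w1[3] * w2[2],
          w1[3] * w2[1] - w1[1] * w2[3],
          w1[1] * w2[2] - w1[2] * w2[1])
  W <- cbind(w1, w2, w3)
  an <- sqrt(rowSums(accel^2))
  cr <- row_cross(accel, mag)
  cn <- sqrt(rowSums(cr^2))
  ok <- an > 1e-9 & cn > 1e-9
  q <- matrix(NA_real_, n, 4)
  for (i in which(ok)) {
    s1 <- accel[i, ] / an[i]
    s2 <- cr[i, ] / cn[i]
    s3 <- c(s1[2] * s2[3] - s1[3] * s2[2],
            s1[3] * s2[1] - s1[1] * s2[3],
            s1[1] * s2[2] - s1[2] * s2[1])
    R <- W %*% t(cbind(s1, s2, s3))
    q[i, ] <- matrix_to_quat(R)
  }
  q
}

#' Complementary-filter sensor fusion to orientation quaternions
#'
#' Estimates the sensor-to-world orientation of one IMU by blending
#' high-frequency gyroscope integration with the low-frequency attitude
#' implied by the accelerometer (gravity) and magnetometer (heading). At each
#' step the previous estimate is advanced by the integrated body angular
#' rate, then pulled toward the accelerometer/magnetometer (TRIAD) attitude
#' by spherical interpolation with weight `gain`.
#'
#' `gain` is the correction weight per sample: `gain = 0` is pure gyroscope
#' integration; the default 0.02 keeps 98% gyroscope weight, trusting the
#' gyro over short horizons while the gravity/field references bound drift.
#' The first sample is initialised from accelerometer + magnetometer alone.
#' Samples with a zero-norm accelerometer reading skip the correction (the
#' prediction is kept) and are reported at the end.
#'
#' @param rec an [imu_recording()].
#' @param gain accelerometer/magnetometer correction weight in `[0, 1)`.
#' @param g_ref,m_ref world-frame gravity reaction (m/s^2) and magnetic field
#'   (microtesla) reference vectors. The defaults match the package's world
#'   convention (Y vertical); only their directions matter.
#' @return an [orientation_series()].
#' @export
complementary_fuse <- function(rec, gain = 0.02,
                               g_ref = c(0, 9.80665, 0),
                               m_ref = c(19, -44, 5)) {
  stopifnot(inherits(rec, "imu_recording") ||
              all(c("time_s", imu_channel_cols) %in% names(rec)))
  if (gain < 0 || gain >= 1) abort("`gain` must lie in [0, 1)")
  fs <- imu_sampling_rate(rec)
  A <- as.matrix(rec[c("ax", "ay", "az")])
  G <- as.matrix(rec[c("gx", "gy", "gz")])
  M <- as.matrix(rec[c("mx", "my", "mz")])
  n <- nrow(A)
  q_meas <- triad_orientation(A, M, g_ref, m_ref)
  q <- matrix(NA_real_, n, 4)
  if (anyNA(q_meas[1, ])) {
    warn("first sample has a degenerate accelerometer/magnetometer reading; initialising at identity")
    q[1, ] <- c(1, 0, 0, 0)
  } else {
    q[1, ] <- q_meas[1, ]
  }
  skipped <- 0L
  for (t in 2:n) {
    q_pred <- quat_multiply(q[t - 1, , drop = FALSE],
                            quat_exp(G[t, , drop = FALSE] / fs))
    if (anyNA(q_meas[t, ]) || gain == 0) {
      if (anyNA(q_meas[t, ])) skipped <- skipped + 1L
      q[t, ] <- q_pred
    } else {
      q[t, ] <- quat_slerp(q_pred, q_meas[t, , drop = FALSE], gain)
    }
  }
  if (skipped > 0) {
    inform(sprintf("complementary_fuse: skipped the attitude correction on %d sample(s) with degenerate readings", skipped))
  }
  orientation_series(rec$time_s, q)
}

#' Relative orientation between a proximal and a distal sensor
#'
#' Joint orientation as the rotation from the proximal into the distal
#' segment frame: `q_joint(t) = conj(q_prox(t)) * q_dist(t)`, evaluated at
#' every shared time stamp.
#'
#' @param proximal,distal [orientation_series()] on the same time base.
#' @return an [orientation_series()] of the joint rotation.
#' @export
relative_orientation <- function(proximal, distal) {
  if (nrow(proximal) != nrow(distal)) {
    abort("proximal and distal orientation series differ in length")
  }
  if (max(abs(proximal$time_s - distal$time_s)) > 1e-9) {
    abort("proximal and distal orientation series are not on a shared time base")
  }
  q <- quat_multiply(quat_conjugate(orientation_quat(proximal)),
                     orientation_quat(distal))
  orientation_series(proximal$time_s, q)
}

#' Intrinsic Z-Y-X Euler angles of an orientation series
#'
#' Decomposes each quaternion in the intrinsic Z (medio-lateral), Y
#' (vertical), X (antero-posterior) rotation sequence. The Z angle is the
#' sagittal-plane angle and is unwrapped over time so it carries no +/-180
#' degree jumps; Y and X are reported as decomposition by-products. Samples
#' whose Y angle comes within 1 degree of +/-90 degrees (gimbal proximity,
#' where Z and X become poorly separated) trigger a warning but are retained.
#'
#' @param joint an [orientation_series()].
#' @return tibble with `time_s`, `z_deg` (sagittal, unwrapped), `y_deg`,
#'   `x_deg`.
#' @export
to_euler_zyx <- function(joint) {
  eul <- quat_to_euler_zyx(orientation_quat(joint))
  y_deg <- rad2deg(eul[, "y"])
  if (any(abs(abs(y_deg) - 90) < 1)) {
    warn("orientation passes within 1 degree of gimbal lock (|Y| near 90 degrees); sagittal angles retained but ill-conditioned there")
  }
  tibble::tibble(
    time_s = joint$time_s,
    z_deg = unwrap_deg(rad2deg(eul[, "z"])),
    y_deg = y_deg,
    x_deg = rad2deg(eul[, "x"])
  )
}

#' Sagittal hip and knee joint angles from three sensor orientations
#'
#' Hip flexion is the sagittal (Z) angle of the pelvis-to-thigh relative
#' rotation; knee flexion the sagittal angle of the thigh-to-shank relative
#' rotation, both in degrees with flexion positive under the package's
#' sensor-mounting convention. An optional static calibration subtracts the
#' mean angle over an initial quiet-standing window, removing constant
#' mounting offsets.
#'
#' @param pelvis,thigh,shank [orientation_series()] on a shared time base.
#' @param calibration_window_s length of the initial quiet-standing window
#'   (s) whose mean angle is subtracted; `0` (default) disables calibration.
#' @return joint-angle tibble: `time_s`, `hip_deg`, `knee_deg`.
#' @export
compute_joint_angles <- function(pelvis, thigh, shank,
                                 calibration_window_s = 0) {
  hip <- to_euler_zyx(relative_orientation(pelvis, thigh))
  knee <- to_euler_zyx(relative_orientation(thigh, shank))
  hip_deg <- hip$z_deg
  knee_deg <- knee$z_deg
  if (calibration_window_s > 0) {
    fs <- check_uniform_time(pelvis$time_s)
    w <- max(1L, min(length(hip_deg), as.integer(round(calibration_window_s * fs))))
    hip_deg <- hip_deg - mean(hip_deg[seq_len(w)])
    knee_deg <- knee_deg - mean(knee_deg[seq_len(w)])
  }
  out <- tibble::tibble(time_s = pelvis$time_s, hip_deg = hip_deg,
                        knee_deg = knee_deg)
  attr(out, "fs") <- check_uniform_time(out$time_s)
  out
}
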