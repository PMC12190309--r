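#' Synthetic single-pass gait kinematics with known ground truth
#'
#' Generates one walkway pass of sagittal hip and knee angles as sinusoids at
#' the stride frequency: `hip = offset + (excursion/2) sin(2 pi f t)` and
#' `knee = offset + (excursion/2) sin(2 pi f t - lag)`, where the hip-knee
#' phase lag is redrawn once per gait cycle from `Normal(lag mean, lag SD)`
#' and blended across cycle boundaries with a cosine cross-fade spanning 5%
#' of the cycle, so the phase track stays smooth for the Hilbert transform.
#' One extra lead-in and lead-out cycle surrounds the analysed strides; this
#' is the "extraneous" data the phase analysis keeps at both ends and later
#' discards.
#'
#' The cycle period is snapped to the sample grid so that each true initial
#' contact (IC) falls exactly on a sample.
#'
#' @param hip_exc,knee_exc joint excursions in degrees (peak-to-peak).
#' @param lag_mean_deg mean hip-knee phase lag (degrees); scalar, or a named
#'   `c(stance =, swing =)` pair giving a smooth region-dependent lag profile
#'   over the gait cycle.
#' @param lag_sd_deg trial-to-trial SD of the per-cycle phase lag (degrees).
#' @param cadence_spm cadence in steps per minute (2 steps per gait cycle).
#' @param n_cycles number of full gait cycles between the first and last IC.
#' @param fs sampling rate (Hz).
#' @param hip_offset_deg,knee_offset_deg constant postural offsets (degrees).
#' @param lead_cycles extra cycles of signal emitted before the first and
#'   after the last IC.
#' @return a `gait_pass` list: `angles` (tibble `time_s`, `hip_deg`,
#'   `knee_deg`), `ic_index` (1-based sample indices of the true ICs),
#'   `lag_deg` (true per-cycle lags), and period/sampling metadata.
#' @examples
#' p <- synth_pass(40, 65, lag_mean_deg = 90, lag_sd_deg = 0, n_cycles = 3)
#' range(p$angles$hip_deg)
#' @export
synth_pass <- function(hip_exc, knee_exc, lag_mean_deg = 60, lag_sd_deg = 10,
                       cadence_spm = 110, n_cycles = 3, fs = 200,
                       hip_offset_deg = 5, knee_offset_deg = 25,
                       lead_cycles = 1) {
  if (cadence_spm <= 0) abort("cadence must be positive")
  if (hip_exc <= 0 || knee_exc <= 0) abort("joint excursions must be positive")
  if (lag_sd_deg < 0) abort("lag SD must be non-negative")
  if (n_cycles < 1) abort("need at least one gait cycle")
  # snap the cycle period to the sample grid so ICs fall on samples
  period_samples <- round(120 / cadence_spm * fs)
  period_s <- period_samples / fs
  lead_samples <- lead_cycles * period_samples
  n <- n_cycles * period_samples + 2 * lead_samples + 1
  t <- (seq_len(n) - 1) / fs
  # gait-cycle coordinate from integer sample arithmetic: exactly k at IC_k
  u <- (seq_len(n) - 1 - lead_samples) / period_samples

  delta <- stats::rnorm(n_cycles, 0, lag_sd_deg)
  lag_deg <- lag_cycle_profile_mean(lag_mean_deg) + delta

  # per-cycle lag offset with 5%-of-cycle cosine cross-fade at internal ICs
  k <- pmin(pmax(floor(u), 0), n_cycles - 1)
  off <- delta[k + 1]
  m <- round(u)
  w <- 0.05
  sel <- m >= 1 & m <= n_cycles - 1 & abs(u - m) <= w / 2
  if (any(sel)) {
    s <- (u[sel] - (m[sel] - w / 2)) / w
    off[sel] <- delta[m[sel]] +
      (delta[m[sel] + 1] - delta[m[sel]]) * (1 - cos(pi * s)) / 2
  }
  lam <- lag_profile(u - floor(u), lag_mean_deg) + off

  # sinpi keeps the waveform (and its zero-crossings) exact at IC samples
  hip <- hip_offset_deg + (hip_exc / 2) * sinpi(2 * u)
  knee <- knee_offset_deg + (knee_exc / 2) * sinpi(2 * u - lam / 180)
  structure(
    list(
      angles = tibble::tibble(time_s = t, hip_deg = hip, knee_deg = knee),
      ic_index = lead_samples + period_samples * (0:n_cycles) + 1L,
      lag_deg = lag_deg,
      n_cycles = n_cycles,
      period_s = period_s,
      fs = fs,
      lead_samples = lead_samples,
      hip_exc = hip_exc, knee_exc = knee_exc
    ),
    class = "gait_pass"
  )
}

# Within-cycle lag profile: constant for a scalar mean; for c(stance, swing)
# the lag moves smoothly stance -> swing over 55-65% of the cycle and back
# over the last 10%, staying periodic and smooth.
lag_profile <- function(frac, lag_mean_deg) {
  if (length(lag_mean_deg) == 1) return(rep(lag_mean_deg, length(frac)))
  stance <- lag_mean_deg[["stance"]]
  swing <- lag_mean_deg[["swing"]]
  wgt <- numeric(length(frac))
  up <- frac >= 0.55 & frac < 0.65
  wgt[up] <- (1 - cos(pi * (frac[up] - 0.55) / 0.10)) / 2
  wgt[frac >= 0.65 & frac < 0.90] <- 1
  dn <- frac >= 0.90
  wgt[dn] <- (1 + cos(pi * (frac[dn] - 0.90) / 0.10)) / 2
  stance + (swing - stance) * wgt
}

lag_cycle_profile_mean <- function(lag_mean_deg) {
  if (length(lag_mean_deg) == 1) return(unname(lag_mean_deg))
  mean(lag_profile(seq(0, 1, length.out = 2001)[-2001], lag_mean_deg))
}

#' Synthetic sagittal shank angular velocity for a pass
#'
#' Emits the event-detection channel implied by a [synth_pass()]: a smooth
#' angular-velocity trace with exactly one dominant positive mid-swing peak
#' per gait cycle (at 75% of the cycle) and a negative-going zero-crossing at
#' every true initial contact. The trace is tapered to zero outside the
#' walking bout so the lead-in/lead-out samples add no spurious peaks.
#'
#' @param pass a `gait_pass` from [synth_pass()].
#' @param noise_sd additive Gaussian noise SD (rad/s).
#' @param peak_rad_s mid-swing peak angular velocity (rad/s).
#' @return numeric vector (rad/s) of the same length as `pass$angles`, with
#'   the true IC sample indices attached as attribute `"ic_index"`.
#' @export
generate_shank_gyro <- function(pass, noise_sd = 0, peak_rad_s = 6) {
  stopifnot(inherits(pass, "gait_pass"))
  if (noise_sd < 0) abort("noise SD must be non-negative")
  n <- nrow(pass$angles)
  period_samples <- as.integer(round(pass$period_s * pass$fs))
  u <- (seq_len(n) - 1 - pass$lead_samples) / period_samples
  nc <- pass$n_cycles
  env <- numeric(n)
  env[u >= -0.5 & u <= nc + 0.25] <- 1
  ramp_in <- u > -0.75 & u < -0.5
  env[ramp_in] <- (1 - cos(pi * (u[ramp_in] + 0.75) / 0.25)) / 2
  ramp_out <- u > nc + 0.25 & u < nc + 0.5
  env[ramp_out] <- (1 + cos(pi * (u[ramp_out] - nc - 0.25) / 0.25)) / 2
  omega <- -peak_rad_s * sinpi(2 * u) * env
  if (noise_sd > 0) omega <- omega + stats::rnorm(n, 0, noise_sd)
  attr(omega, "ic_index") <- pass$ic_index
  omega
}

# hardware ranges of the emulated IMU
imu_range <- list(accel = 16 * 9.80665, gyro = 2000 * pi / 180, mag = 190)

#' Raw IMU emission for a synthetic pass
#'
#' Converts the joint-angle ground truth of a [synth_pass()] into raw sensor
#' streams for the pelvis, right-thigh and right-shank IMUs. Segment
#' orientations are pure sagittal (medio-lateral axis) rotations implied by
#' the hip and knee angles with the pelvis held level; each sensor then reads
#' gravity rotated into its frame (accelerometer), the body angular rate
#' obtained by differentiating its orientation (gyroscope) and a constant
#' world magnetic field rotated into its frame (magnetometer), plus optional
#' Gaussian noise. Values beyond the emulated hardware ranges (+/-16 g,
#' +/-2000 deg/s, +/-1.9 Gauss) are clipped with a warning.
#'
#' The world frame follows the joint-angle axis convention used throughout:
#' X antero-posterior, Y vertical (gravity along -Y acting, accelerometer
#' reading +Y at rest), Z medio-lateral.
#'
#' @inheritParams generate_shank_gyro
#' @param noise list with `accel_sd`, `gyro_sd`, `mag_sd` (SI units).
#' @param g_world,m_world world-frame gravity reaction (m/s^2) and magnetic
#'   field (microtesla) used for the emission; keep in sync with the fusion
#'   references.
#' @return named list of three [imu_recording()]s: `pelvis`, `thigh_r`,
#'   `shank_r`.
#' @export
generate_raw_imu <- function(pass,
                             noise = list(accel_sd = 0, gyro_sd = 0, mag_sd = 0),
                             g_world = c(0, 9.80665, 0),
                             m_world = c(19, -44, 5)) {
  stopifnot(inherits(pass, "gait_pass"))
  t <- pass$angles$time_s
  fs <- pass$fs
  hip <- deg2rad(pass$angles$hip_deg)
  knee <- deg2rad(pass$angles$knee_deg)
  ml_axis <- c(0, 0, 1)
  q_pelvis <- matrix(rep(c(1, 0, 0, 0), length(t)), ncol = 4, byrow = TRUE)
  q_thigh <- quat_from_axis_angle(ml_axis, hip)
  q_shank <- quat_multiply(q_thigh, quat_from_axis_angle(ml_axis, knee))
  emit <- function(q, placement) {
    n <- nrow(q)
    qc <- quat_conjugate(q)
    accel <- quat_rotate(qc, matrix(g_world, n, 3, byrow = TRUE))
    mag <- quat_rotate(qc, matrix(m_world, n, 3, byrow = TRUE))
    qrel <- quat_multiply(quat_conjugate(q[-n, , drop = FALSE]),
                          q[-1, , drop = FALSE])
    gyro <- quat_log(qrel) * fs
    gyro <- rbind(gyro[1, , drop = FALSE], gyro)
    if (noise$accel_sd > 0) accel <- accel + stats::rnorm(3 * n, 0, noise$accel_sd)
    if (noise$gyro_sd > 0) gyro <- gyro + stats::rnorm(3 * n, 0, noise$gyro_sd)
    if (noise$mag_sd > 0) mag <- mag + stats::rnorm(3 * n, 0, noise$mag_sd)
    clip <- function(x, lim, what) {
      if (any(abs(x) > lim)) {
        warn(sprintf("%s %s exceeds the emulated hardware range; clipping", placement, what))
        x <- pmin(pmax(x, -lim), lim)
      }
      x
    }
    accel <- clip(accel, imu_range$accel, "acceleration")
    gyro <- clip(gyro, imu_range$gyro, "angular velocity")
    mag <- clip(mag, imu_range$mag, "magnetic field")
    imu_recording(t, accel, gyro, mag, placement = placement)
  }
  list(pelvis = emit(q_pelvis, "pelvis"),
       thigh_r = emit(q_thigh, "thigh_r"),
       shank_r = emit(q_shank, "shank_r"))
}

rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
  x
}

#' Simulate a synthetic walking cohort with ground truth
#'
#' Draws participants from one or more [cohort_spec()]s and generates every
#' walkway pass at each speed condition: joint-angle waveforms, the shank
#' angular-velocity event channel and (optionally) raw IMU streams. Each
#' participant x condition receives a true walking speed and true hip/knee
#' excursions drawn from the group distributions; each participant receives a
#' habitual mean phase lag (drawn with the between-participant lag SD) and
#' each gait cycle a true lag around it (trial-to-trial lag SD). All draws are recorded in the returned truth
#' tables, which downstream recovery tests and analyses can join against.
#'
#' Gait cycles per pass are derived from the condition's step count (two
#' steps per right-side gait cycle, at least two cycles).
#'
#' @param specs a `cohort_spec` or list of them (default: the shipped PD and
#'   HOA parameter sets).
#' @param seed integer RNG seed; `NULL` leaves the ambient RNG state alone.
#' @param emit_raw also emit raw IMU streams per pass (slower).
#' @param noisy apply the spec's sensor-noise SDs (set `FALSE` for exact
#'   ground-truth signals).
#' @param lead_cycles lead-in/out cycles around each pass.
#' @return a `synthetic_cohort` list with
#'   `passes` (tibble: participant, group, speed_cond, pass, fs,
#'   `signals` list-column of per-sample tibbles, `imu` list-column,
#'   `pass_obj` list-column of `gait_pass` truth),
#'   `participants` (per participant x condition truth: speed, excursions),
#'   `lags` (per-cycle true phase lags) and `events` (true IC indices).
#' @examples
#' spec <- default_cohort_spec("hoa")
#' spec$n_participants <- 2
#' spec$passes_per_speed <- 1
#' coh <- simulate_cohort(spec, seed = 1)
#' coh$participants
#' @export
simulate_cohort <- function(specs = list(default_cohort_spec("pd"),
                                         default_cohort_spec("hoa")),
                            seed = NULL, emit_raw = FALSE, noisy = TRUE,
                            lead_cycles = 1) {
  if (inherits(specs, "cohort_spec")) specs <- list(specs)
  seed <- seed %||% specs[[1]]$seed
  if (!is.null(seed)) set.seed(seed)
  passes <- list()
  participants <- list()
  lags <- list()
  events <- list()
  for (spec in specs) {
    for (i in seq_len(spec$n_participants)) {
      pid <- sprintf("%s%02d", spec$group, i)
      # habitual coordination strategy: one lag-profile shift per participant
      lag_shift <- stats::rnorm(1, 0, spec$lag_between_sd_deg)
      lag_mean_i <- spec$lag_mean_deg + lag_shift
      for (cond in c("slow", "preferred", "fast")) {
        cc <- spec$conditions[[cond]]
        speed <- rnorm_pos(1, cc$speed_mean, cc$speed_sd)
        hip_exc <- rnorm_pos(1, cc$hip_exc_mean, cc$hip_exc_sd)
        knee_exc <- rnorm_pos(1, cc$knee_exc_mean, cc$knee_exc_sd)
        n_cycles <- max(2L, as.integer(ceiling(cc$steps_per_pass / 2)))
        participants[[length(participants) + 1]] <- tibble::tibble(
          participant = pid, group = spec$group, speed_cond = cond,
          speed_mps = speed, hip_excursion_deg = hip_exc,
          knee_excursion_deg = knee_exc, cadence_spm = cc$cadence_spm,
          lag_mean_deg = lag_cycle_profile_mean(lag_mean_i),
          n_cycles_per_pass = n_cycles
        )
        for (p in seq_len(spec$passes_per_speed)) {
          po <- synth_pass(
            hip_exc, knee_exc,
            lag_mean_deg = lag_mean_i, lag_sd_deg = spec$lag_sd_deg,
            cadence_spm = cc$cadence_spm, n_cycles = n_cycles,
            fs = spec$fs_hz, hip_offset_deg = spec$hip_offset_deg,
            knee_offset_deg = spec$knee_offset_deg, lead_cycles = lead_cycles
          )
          gyro <- generate_shank_gyro(
            po, noise_sd = if (noisy) spec$noise$gyro_sd else 0,
            peak_rad_s = 3 + 2.5 * speed
          )
          sig <- po$angles
          sig$shank_gyro_z <- as.numeric(gyro)
          imu <- if (emit_raw) {
            generate_raw_imu(po, noise = if (noisy) spec$noise else
              list(accel_sd = 0, gyro_sd = 0, mag_sd = 0))
          }
          passes[[length(passes) + 1]] <- tibble::tibble(
            participant = pid, group = spec$group, speed_cond = cond,
            pass = p, fs = spec$fs_hz,
            signals = list(sig), imu = list(imu), pass_obj = list(po)
          )
          lags[[length(lags) + 1]] <- tibble::tibble(
            participant = pid, speed_cond = cond, pass = p,
            cycle = seq_along(po$lag_deg), lag_deg = po$lag_deg
          )
          events[[length(events) + 1]] <- tibble::tibble(
            participant = pid, speed_cond = cond, pass = p,
            ic_index = po$ic_index
          )
        }
      }
    }
  }
  structure(
    list(passes = dplyr::bind_rows(passes),
         participants = dplyr::bind_rows(participants),
         lags = dplyr::bind_rows(lags),
         events = dplyr::bind_rows(events)),
    class = "synthetic_cohort"
  )
}

#' @rdname simulate_cohort
#' @param spec a single `cohort_spec`.
#' @export
generate_joint_waveforms <- function(spec, seed = NULL) {
  simulate_cohort(list(spec), seed = seed, emit_raw = FALSE, noisy = FALSE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d passes, %d participant x condition cells\n",
              nrow(x$passes), nrow(x$participants)))
  print(dplyr::count(x$participants, .data$group, .data$speed_cond))
  invisible(x)
}
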