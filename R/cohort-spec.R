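#' Cohort specification for the synthetic gait generator
#'
#' A `cohort_spec` collects everything the generator needs for one group:
#' per-speed walking-speed and joint-excursion distributions (between-subject
#' mean and SD), cadence, hip-knee phase-lag parameters (the mean lag sets the
#' average coordination pattern; the trial-to-trial lag SD is the generative
#' analogue of Deviation Phase), pass structure and sensor-noise levels.
#'
#' Shipped defaults (`default_cohort_spec("pd")` / `"hoa"`) are calibrated to
#' published descriptive statistics for older adults with and without
#' Parkinson's disease walking at slow, preferred and fast speeds (e.g. PD
#' slow speed 0.65 +/- 0.17 m/s; HOA preferred hip excursion 40.5 +/- 7.6
#' degrees) and live as plain YAML under `inst/extdata/`.
#'
#' @param group group label, `"PD"` or `"HOA"`.
#' @param n_participants number of participants (>= 2).
#' @param passes_per_speed walkway passes recorded per speed condition.
#' @param fs_hz IMU sampling rate in Hz.
#' @param conditions named list (`slow`, `preferred`, `fast`), each a list
#'   with `speed_mean`, `speed_sd` (m/s), `hip_exc_mean`, `hip_exc_sd`,
#'   `knee_exc_mean`, `knee_exc_sd` (degrees), `cadence_spm` (steps/min) and
#'   `steps_per_pass`.
#' @param lag_mean_deg mean hip-knee phase lag in degrees; either a single
#'   number or a named length-2 vector `c(stance = , swing = )` for a
#'   region-dependent lag profile over the gait cycle.
#' @param lag_sd_deg trial-to-trial (per gait cycle) SD of the phase lag.
#' @param lag_between_sd_deg between-participant SD of the mean phase lag:
#'   each participant's habitual coordination strategy is drawn once from
#'   `Normal(lag_mean_deg, lag_between_sd_deg)`.
#' @param hip_offset_deg,knee_offset_deg constant angular offsets added to
#'   the sinusoidal waveforms (mean joint posture).
#' @param noise list with `accel_sd` (m/s^2), `gyro_sd` (rad/s), `mag_sd`
#'   (microtesla) additive Gaussian sensor-noise SDs.
#' @param seed optional default RNG seed carried by the spec.
#' @return a `cohort_spec` object (validated list).
#' @export
cohort_spec <- function(group, n_participants, conditions,
                        passes_per_speed = 10, fs_hz = 200,
                        lag_mean_deg = 60, lag_sd_deg = 10,
                        lag_between_sd_deg = 7,
                        hip_offset_deg = 5, knee_offset_deg = 25,
                        noise = list(accel_sd = 0.05, gyro_sd = 0.005,
                                     mag_sd = 0.3),
                        seed = NULL) {
  group <- match.arg(toupper(group), c("PD", "HOA"))
  if (!is.numeric(n_participants) || n_participants < 2) {
    abort("`n_participants` must be at least 2")
  }
  if (!all(c("slow", "preferred", "fast") %in% names(conditions))) {
    abort("`conditions` must contain entries slow, preferred and fast")
  }
  for (cond in names(conditions)) {
    cc <- conditions[[cond]]
    need <- c("speed_mean", "speed_sd", "hip_exc_mean", "hip_exc_sd",
              "knee_exc_mean", "knee_exc_sd", "cadence_spm", "steps_per_pass")
    missing <- setdiff(need, names(cc))
    if (length(missing) > 0) {
      abort(sprintf("condition '%s' is missing: %s", cond,
                    paste(missing, collapse = ", ")))
    }
    if (cc$speed_mean <= 0) abort(sprintf("'%s': walking speed must be positive", cond))
    if (cc$hip_exc_mean <= 0 || cc$knee_exc_mean <= 0) {
      abort(sprintf("'%s': joint excursions must be positive", cond))
    }
    if (cc$cadence_spm <= 0) abort(sprintf("'%s': cadence must be positive", cond))
    if (any(c(cc$speed_sd, cc$hip_exc_sd, cc$knee_exc_sd) < 0)) {
      abort(sprintf("'%s': SDs must be non-negative", cond))
    }
  }
  if (any(lag_sd_deg < 0) || lag_between_sd_deg < 0 || any(unlist(noise) < 0)) {
    abort("lag SD and sensor-noise SDs must be non-negative")
  }
  if (!length(lag_mean_deg) %in% c(1, 2)) {
    abort("`lag_mean_deg` must be a scalar or c(stance=, swing=)")
  }
  structure(
    list(group = group,
         n_participants = as.integer(n_participants),
         passes_per_speed = as.integer(passes_per_speed),
         fs_hz = fs_hz,
         conditions = conditions,
         lag_mean_deg = lag_mean_deg,
         lag_sd_deg = lag_sd_deg,
         lag_between_sd_deg = lag_between_sd_deg,
         hip_offset_deg = hip_offset_deg,
         knee_offset_deg = knee_offset_deg,
         noise = noise,
         seed = seed),
    class = "cohort_spec"
  )
}

#' @rdname cohort_spec
#' @export
default_cohort_spec <- function(group = c("pd", "hoa")) {
  group <- match.arg(tolower(group), c("pd", "hoa"))
  path <- system.file("extdata", paste0("cohort_", group, ".yaml"),
                      package = "gaitcoord", mustWork = TRUE)
  read_cohort_spec(path)
}

#' @rdname cohort_spec
#' @param path path to a cohort YAML file.
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_spec(
    group = y$group,
    n_participants = y$n_participants,
    conditions = y$conditions,
    passes_per_speed = y$passes_per_speed %||% 10,
    fs_hz = y$fs_hz %||% 200,
    lag_mean_deg = unlist(y$lag_mean_deg),
    lag_sd_deg = y$lag_sd_deg %||% 10,
    lag_between_sd_deg = y$lag_between_sd_deg %||% 7,
    hip_offset_deg = y$hip_offset_deg %||% 5,
    knee_offset_deg = y$knee_offset_deg %||% 25,
    noise = y$noise %||% list(accel_sd = 0.05, gyro_sd = 0.005, mag_sd = 0.3),
    seed = y$seed
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> group %s: %d participants, %d passes/speed, %g Hz\n",
              x$group, x$n_participants, x$passes_per_speed, x$fs_hz))
  for (cond in c("slow", "preferred", "fast")) {
    cc <- x$conditions[[cond]]
    cat(sprintf("  %-9s speed %.2f (%.2f) m/s; hip %.1f (%.1f), knee %.1f (%.1f) deg; %g steps/min\n",
                cond, cc$speed_mean, cc$speed_sd, cc$hip_exc_mean, cc$hip_exc_sd,
                cc$knee_exc_mean, cc$knee_exc_sd, cc$cadence_spm))
  }
  cat(sprintf("  phase lag %s deg (trial SD %g, between-participant SD %g)\n",
              paste(x$lag_mean_deg, collapse = "/"), x$lag_sd_deg,
              x$lag_between_sd_deg))
  invisible(x)
}
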