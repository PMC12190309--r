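#' Instantaneous phase of a joint-angle signal via the Hilbert transform
#'
#' Centers the signal (subtracting the midpoint `(max + min) / 2` of the
#' analysis span), forms the analytic signal on a padded copy, and returns
#' the unwrapped instantaneous phase `atan2(imag, real)` in degrees with the
#' pad removed. Padding keeps the transform's edge distortion out of the
#' analysed span. Two padding sources are supported:
#'
#' * `span`: genuine neighbouring data already present in `x` (the
#'   "extraneous" samples around a walking bout) act as the pad -- the
#'   preferred route inside the pipeline;
#' * `pad_n`: for a standalone cyclic signal, a periodic continuation of
#'   `pad_n` samples is synthesised at each end. The dominant period is
#'   estimated from the first autocorrelation peak beyond the first zero
#'   crossing; if the signal is not convincingly cyclic (peak correlation
#'   below 0.6) the transform runs unpadded instead, since an ill-matched
#'   extension distorts the phase more than the finite-window edges do.
#'
#' @param x numeric signal (joint angle, degrees).
#' @param pad_n number of samples of synthetic padding added at each end
#'   when `span` is `NULL`. A good value is one gait cycle or more.
#' @param span optional `c(first, last)` sample indices of the analysis span
#'   within `x`; samples outside it act as the pad and are removed from the
#'   output.
#' @param joint joint name used in error messages.
#' @return numeric vector of unwrapped phase angles (degrees) for the
#'   analysis span.
#' @examples
#' t <- seq(0, 5, by = 1 / 200)
#' ph <- hilbert_phase(sin(2 * pi * t), pad_n = 200)
#' # phase advances 360 degrees per second
#' @export
hilbert_phase <- function(x, pad_n = 0, span = NULL, joint = "signal") {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) abort("signal too short for phase analysis")
  if (!is.null(span)) {
    span <- as.integer(span)
    if (span[1] < 1 || span[2] > n || span[1] >= span[2]) {
      abort("`span` must select a non-empty window inside the signal")
    }
    xa <- x
  } else {
    span <- c(1L, n)
    xa <- x
  }
  core <- xa[span[1]:span[2]]
  lo <- min(core)
  hi <- max(core)
  if (hi - lo < .Machine$double.eps^0.5) {
    abort(sprintf("phase of the %s is undefined: the signal is constant over the analysis span", joint))
  }
  xa <- xa - (hi + lo) / 2
  if (is.null(dim(span)) && pad_n > 0 && span[1] == 1L && span[2] == n) {
    P <- estimate_period(xa)
    if (!is.na(P)) {
      pad_n <- as.integer(pad_n)
      front <- xa[((-(pad_n:1)) %% P) + 1]
      back <- xa[(((n - 1) + seq_len(pad_n)) %% P) + 1]
      xa <- c(front, xa, back)
      span <- c(pad_n + 1L, pad_n + n)
    }
  }
  z <- analytic_signal(xa)
  phase <- unwrap_deg(rad2deg(atan2(Im(z), Re(z))))
  phase[span[1]:span[2]]
}

# Dominant period in samples from the first autocorrelation peak after the
# first zero crossing; NA when the signal is not convincingly cyclic.
estimate_period <- function(x, min_peak = 0.6) {
  ac <- stats::acf(x - mean(x), lag.max = floor(length(x) / 2),
                   plot = FALSE)$acf[-1]
  z <- which(ac < 0)[1]
  if (is.na(z) || z >= length(ac)) return(NA_integer_)
  P <- which.max(ac[z:length(ac)]) + z - 1L
  if (ac[P] < min_peak) return(NA_integer_)
  as.integer(P)
}

#' Continuous relative phase between two joints
#'
#' The CRP angle is the absolute hip-knee phase difference folded onto the
#' `[0, 180]` degree scale: `d = |phi_hip - phi_knee| mod 360`, then
#' `CRP = min(d, 360 - d)`. Values near 0 indicate in-phase (synchronous)
#' joint motion, values near 180 anti-phase motion. The fold makes
#' `crp(a, b)` exactly symmetric in its arguments.
#'
#' @param hip_phase,knee_phase unwrapped phase series in degrees, aligned
#'   sample by sample.
#' @return numeric CRP series in degrees, bounded to `[0, 180]`.
#' @export
crp <- function(hip_phase, knee_phase) {
  if (length(hip_phase) != length(knee_phase)) {
    abort("phase series differ in length")
  }
  d <- abs(hip_phase - knee_phase) %% 360
  pmin(d, 360 - d)
}

#' MARP and DP summaries of a set of CRP cycles
#'
#' Mean Absolute Relative Phase (MARP) is the mean over the 101 gait-cycle
#' nodes of the across-cycle (ensemble) mean CRP curve: the participant's
#' average coordination strategy. Deviation Phase (DP) is the mean over the
#' nodes of the across-cycle sample standard deviation (n - 1 denominator):
#' the participant's coordination variability. DP requires at least two
#' cycles and is returned as `NA` (with a warning) for a single cycle.
#'
#' @param crp_cycles a `gait_cycles` tibble with columns `cycle`, `pct` and
#'   `crp_deg` (101 nodes per cycle), or an n_cycles x 101 numeric matrix.
#' @return one-row tibble: `marp_deg`, `dp_deg`, `n_cycles`.
#' @export
marp_dp <- function(crp_cycles) {
  m <- crp_cycle_matrix(crp_cycles)
  if (nrow(m) == 0) abort("no CRP cycles: MARP is undefined")
  marp <- mean(colMeans(m))
  if (nrow(m) < 2) {
    warn("only one CRP cycle: DP is undefined (NA)")
    dp <- NA_real_
  } else {
    dp <- mean(apply(m, 2, stats::sd))
  }
  tibble::tibble(marp_deg = marp, dp_deg = dp, n_cycles = nrow(m))
}

crp_cycle_matrix <- function(crp_cycles) {
  if (is.matrix(crp_cycles)) return(crp_cycles)
  stopifnot(all(c("cycle", "pct", "crp_deg") %in% names(crp_cycles)))
  wide <- tidyr::pivot_wider(crp_cycles[c("cycle", "pct", "crp_deg")],
                             names_from = "pct", values_from = "crp_deg")
  as.matrix(wide[-1])
}

#' Ensemble of CRP cycles for one participant and speed
#'
#' Bundles a participant's CRP cycles with their ensemble mean curve,
#' pointwise SD curve and the MARP/DP scalars. The curves are what enters
#' the waveform-level (SPM) group comparison; the scalars enter the
#' ANCOVA-level analysis.
#'
#' @param crp_cycles as in [marp_dp()].
#' @param participant,speed_cond optional labels carried along.
#' @return a `crp_ensemble` object with `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @export
crp_ensemble <- function(crp_cycles, participant = NA_character_,
                         speed_cond = NA_character_) {
  m <- crp_cycle_matrix(crp_cycles)
  if (nrow(m) == 0) abort("no CRP cycles: ensemble is undefined")
  summ <- marp_dp(m)
  structure(
    list(
      cycles = m,
      curves = tibble::tibble(
        pct = seq(0, 100, length.out = 101L),
        crp_mean_deg = colMeans(m),
        crp_sd_deg = if (nrow(m) > 1) apply(m, 2, stats::sd) else rep(NA_real_, 101L)
      ),
      marp_deg = summ$marp_deg,
      dp_deg = summ$dp_deg,
      n_cycles = nrow(m),
      participant = participant,
      speed_cond = speed_cond
    ),
    class = "crp_ensemble"
  )
}

#' @export
print.crp_ensemble <- function(x, ...) {
  cat(sprintf("<crp_ensemble> %s %s: %d cycles, MARP %.1f deg, DP %s deg\n",
              x$participant, x$speed_cond, x$n_cycles, x$marp_deg,
              ifelse(is.na(x$dp_deg), "NA", sprintf("%.1f", x$dp_deg))))
  invisible(x)
}

#' @rdname crp_ensemble
#' @param x a `crp_ensemble`.
#' @param ... unused.
#' @export
tidy.crp_ensemble <- function(x, ...) {
  tibble::tibble(
    participant = x$participant, speed_cond = x$speed_cond,
    pct = x$curves$pct,
    crp_mean_deg = x$curves$crp_mean_deg,
    crp_sd_deg = x$curves$crp_sd_deg
  )
}

#' @rdname crp_ensemble
#' @export
glance.crp_ensemble <- function(x, ...) {
  tibble::tibble(
    participant = x$participant, speed_cond = x$speed_cond,
    marp_deg = x$marp_deg, dp_deg = x$dp_deg, n_cycles = x$n_cycles
  )
}

#' Per-pass CRP analysis: phase, fold, segment, normalize
#'
#' Runs the coordination chain on one walkway pass: instantaneous phase of
#' hip and knee over the span between the first and last initial contact
#' (samples outside that span act as the Hilbert pad and are then
#' discarded), CRP of the whole span, and segmentation of the CRP series
#' into 101-point gait cycles. Computing CRP on the continuous pass before
#' segmenting avoids re-introducing per-cycle edge artefacts.
#'
#' @param signals tibble with `time_s`, `hip_deg`, `knee_deg`.
#' @param ic_index integer IC sample indices within `signals` (at least 2).
#' @param fs sampling rate (Hz); defaults to the `time_s` spacing.
#' @return a `gait_cycles` tibble of CRP cycles (`cycle`, `pct`, `crp_deg`).
#' @export
pass_crp_cycles <- function(signals, ic_index, fs = NULL) {
  fs <- fs %||% attr(signals, "fs") %||% check_uniform_time(signals$time_s)
  ic <- sort(as.integer(ic_index))
  if (length(ic) < 2) {
    return(segment_and_normalize(
      tibble::tibble(time_s = numeric(), crp_deg = numeric()), integer()))
  }
  span <- c(ic[1], ic[length(ic)])
  hip_phase <- hilbert_phase(signals$hip_deg, span = span, joint = "hip")
  knee_phase <- hilbert_phase(signals$knee_deg, span = span, joint = "knee")
  crp_series <- crp(hip_phase, knee_phase)
  crp_tbl <- tibble::tibble(
    time_s = signals$time_s[span[1]:span[2]],
    crp_deg = crp_series
  )
  attr(crp_tbl, "fs") <- fs
  segment_and_normalize(crp_tbl, ic - span[1] + 1L)
}
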