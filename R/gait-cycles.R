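#' Initial-contact detection from shank angular velocity
#'
#' Finds gait events on the sagittal-plane angular velocity of the shank:
#' mid-swing peaks are local maxima above a height threshold, and each
#' initial contact (IC) is the first negative-going zero-crossing after its
#' mid-swing peak. Under the package's sign convention the mid-swing angular
#' velocity is positive; recordings using the opposite convention can set
#' `convention = "negative_midswing"` to detect on the flipped signal.
#'
#' A peak with no subsequent zero-crossing is dropped (and counted in the
#' `dropped_peaks` attribute); a signal with no qualifying peaks returns an
#' empty event table with a warning.
#'
#' @param gyro_z numeric sagittal angular-velocity series (rad/s), ideally
#'   low-pass filtered first.
#' @param fs sampling rate (Hz).
#' @param min_peak_rad_s height threshold for mid-swing peaks (rad/s).
#' @param min_separation_s minimum spacing between mid-swing peaks (s).
#' @param convention `"positive_midswing"` (default) or
#'   `"negative_midswing"`.
#' @return tibble of gait events with one row per detected stride:
#'   `midswing_index`, `ic_index` (1-based sample indices, strictly
#'   increasing, each IC after its peak).
#' @export
detect_initial_contacts <- function(gyro_z, fs, min_peak_rad_s = 0.5,
                                    min_separation_s = 0.3,
                                    convention = c("positive_midswing",
                                                   "negative_midswing")) {
  convention <- match.arg(convention)
  x <- as.numeric(gyro_z)
  if (convention == "negative_midswing") x <- -x
  empty <- tibble::tibble(midswing_index = integer(), ic_index = integer())
  # peak pattern tolerates flat tops (zero first differences at a peak)
  pk <- pracma::findpeaks(x, minpeakheight = min_peak_rad_s,
                          peakpat = "[+]{1,}[0]*[-]{1,}")
  if (is.null(pk)) {
    warn("no mid-swing peaks found; returning an empty event set")
    return(empty)
  }
  peaks <- sort(pk[, 2])
  # enforce the minimum peak separation, keeping the earlier peak
  min_sep <- max(1L, as.integer(round(min_separation_s * fs)))
  if (length(peaks) > 1) {
    keep <- c(TRUE, diff(peaks) >= min_sep)
    while (!all(keep)) {
      peaks <- peaks[keep]
      keep <- c(TRUE, diff(peaks) >= min_sep)
    }
  }
  n <- length(x)
  ic <- integer(0)
  ms <- integer(0)
  dropped <- 0L
  last_ic <- 0L
  for (p in peaks) {
    if (p <= last_ic) next  # peak before the previous IC's crossing resolved
    i <- p
    while (i < n && !(x[i] > 0 && x[i + 1] <= 0)) i <- i + 1L
    if (i >= n) {
      dropped <- dropped + 1L
      next
    }
    ms <- c(ms, p)
    ic <- c(ic, i + 1L)
    last_ic <- i + 1L
  }
  if (dropped > 0) {
    inform(sprintf("detect_initial_contacts: dropped %d peak(s) with no subsequent zero-crossing", dropped))
  }
  out <- tibble::tibble(midswing_index = as.integer(ms), ic_index = as.integer(ic))
  attr(out, "dropped_peaks") <- dropped
  out
}

#' Segment a pass into time-normalized gait cycles
#'
#' Splits joint-angle series at consecutive initial contacts: cycle k spans
#' `[IC_k, IC_{k+1})` and each joint's waveform is linearly interpolated onto
#' 101 evenly spaced points (0 to 100% of the gait cycle, both endpoints
#' included). Cycles with implausible durations (outside
#' `[min_duration_s, max_duration_s]`) are discarded and reported. Per-cycle
#' excursions (max minus min of the unnormalized waveform) and durations are
#' attached as the `"cycle_info"` attribute, retrievable with
#' [cycle_info()].
#'
#' @param angles tibble with `time_s` and one or more signal columns
#'   (typically `hip_deg`, `knee_deg`; any numeric column other than
#'   `time_s` is segmented).
#' @param events event tibble from [detect_initial_contacts()] (or any
#'   data frame with an `ic_index` column), or an integer vector of IC
#'   sample indices.
#' @param min_duration_s,max_duration_s physiological gate on cycle duration.
#' @return a `gait_cycles` tibble in long-by-node form: `cycle`, `pct`
#'   (0..100) and one column per segmented signal; zero rows when fewer than
#'   two ICs are available.
#' @export
segment_and_normalize <- function(angles, events, min_duration_s = 0.4,
                                  max_duration_s = 2.5) {
  ic <- if (is.data.frame(events)) events$ic_index else as.integer(events)
  ic <- sort(unique(as.integer(ic)))
  sig_cols <- setdiff(names(angles)[vapply(angles, is.numeric, logical(1))],
                      "time_s")
  empty <- tibble::tibble(cycle = integer(), pct = numeric())
  for (cl in sig_cols) empty[[cl]] <- numeric()
  class(empty) <- c("gait_cycles", class(empty))
  if (length(ic) < 2) {
    attr(empty, "cycle_info") <- tibble::tibble(
      cycle = integer(), start_index = integer(), end_index = integer(),
      duration_s = numeric())
    return(empty)
  }
  if (ic[1] < 1 || ic[length(ic)] > nrow(angles)) {
    abort("initial-contact indices fall outside the angle series")
  }
  fs <- attr(angles, "fs") %||% check_uniform_time(angles$time_s)
  waves <- list()
  info <- list()
  kept <- 0L
  dropped <- 0L
  for (k in seq_len(length(ic) - 1)) {
    a <- ic[k]
    b <- ic[k + 1]
    duration <- (b - a) / fs
    if (duration < min_duration_s || duration > max_duration_s) {
      dropped <- dropped + 1L
      next
    }
    kept <- kept + 1L
    row <- tibble::tibble(cycle = kept, pct = seq(0, 100, length.out = 101L))
    inf <- tibble::tibble(cycle = kept, start_index = a, end_index = b,
                          duration_s = duration)
    for (cl in sig_cols) {
      seg <- angles[[cl]][a:b]
      row[[cl]] <- resample_101(seg, 1, length(seg))
      inf[[paste0(cl, "_excursion")]] <- max(seg) - min(seg)
    }
    waves[[kept]] <- row
    info[[kept]] <- inf
  }
  if (dropped > 0) {
    inform(sprintf("segment_and_normalize: discarded %d cycle(s) outside the %g-%g s duration gate",
                   dropped, min_duration_s, max_duration_s))
  }
  if (kept == 0) {
    attr(empty, "cycle_info") <- tibble::tibble(
      cycle = integer(), start_index = integer(), end_index = integer(),
      duration_s = numeric())
    return(empty)
  }
  out <- dplyr::bind_rows(waves)
  attr(out, "cycle_info") <- dplyr::bind_rows(info)
  class(out) <- c("gait_cycles", class(out))
  out
}

#' @rdname segment_and_normalize
#' @param cycles a `gait_cycles` object.
#' @export
cycle_info <- function(cycles) {
  attr(cycles, "cycle_info") %||%
    abort("no cycle metadata attached; was this produced by segment_and_normalize()?")
}

#' Mean joint excursion across gait cycles
#'
#' The per-cycle excursion is the range (max minus min) of the unnormalized
#' joint waveform within the cycle; the summary is its mean across all
#' retained cycles, per joint. Excursions are invariant to constant angular
#' offsets and never negative.
#'
#' @param cycles a `gait_cycles` object from [segment_and_normalize()], or a
#'   `cycle_info()` tibble with `*_excursion` columns (rows from several
#'   passes may be bound together before averaging).
#' @return tibble with `joint`, `mean_excursion_deg`, `sd_excursion_deg`,
#'   `n_cycles`.
#' @export
joint_excursion <- function(cycles) {
  info <- if (inherits(cycles, "gait_cycles")) cycle_info(cycles) else cycles
  exc_cols <- grep("_excursion$", names(info), value = TRUE)
  if (nrow(info) == 0 || length(exc_cols) == 0) {
    abort("no cycles available: joint excursion is undefined")
  }
  purrr::map_dfr(exc_cols, function(cl) {
    tibble::tibble(
      joint = sub("(_deg)?_excursion$", "", cl),
      mean_excursion_deg = mean(info[[cl]]),
      sd_excursion_deg = stats::sd(info[[cl]]),
      n_cycles = nrow(info)
    )
  })
}
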