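#' IMU recordings: construction, CSV input/output and unit conversion
#'
#' An IMU recording is a tibble with one row per sample and columns
#' `time_s` (seconds), `ax, ay, az` (acceleration, m/s^2), `gx, gy, gz`
#' (angular velocity, rad/s) and `mx, my, mz` (magnetic field, microtesla),
#' carrying the sensor placement and sampling rate as attributes. Channels
#' follow the conventional wearable-sensor units after import; native export
#' units (g, deg/s, Gauss) are converted on read.
#'
#' The CSV dialect is deliberately plain: comma-separated, one header row
#' with exactly the column names above, optionally preceded by a comment line
#' `# units: native` (or `# units: si`). With `units = "native"` (or the
#' comment flag) acceleration is read in g, angular velocity in deg/s and
#' magnetic field in Gauss, and converted to m/s^2, rad/s and microtesla.
#'
#' @param accel,gyro,mag n x 3 matrices of sensor channels (SI units).
#' @param time_s time vector in seconds, strictly increasing and uniform.
#' @param placement sensor placement label, one of `"pelvis"`, `"thigh_r"`,
#'   `"shank_r"`, `"foot_r"`, `"other"`.
#' @return `imu_recording()` and `read_imu_csv()` return an `imu_recording`
#'   tibble.
#' @examples
#' t <- seq(0, 1, by = 1 / 200)
#' rec <- imu_recording(
#'   time_s = t,
#'   accel = cbind(0, 9.80665 + 0 * t, 0),
#'   gyro = matrix(0, length(t), 3),
#'   mag = cbind(19, -44 + 0 * t, 5),
#'   placement = "pelvis"
#' )
#' imu_sampling_rate(rec)
#' @export
imu_recording <- function(time_s, accel, gyro, mag,
                          placement = c("pelvis", "thigh_r", "shank_r",
                                        "foot_r", "other")) {
  placement <- match.arg(placement)
  n <- length(time_s)
  for (nm in c("accel", "gyro", "mag")) {
    m <- get(nm)
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != 3) {
      abort(sprintf("`%s` must be an n x 3 matrix matching `time_s`", nm))
    }
  }
  fs <- check_uniform_time(time_s)
  out <- tibble::tibble(
    time_s = as.numeric(time_s),
    ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
    gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
    mx = mag[, 1], my = mag[, 2], mz = mag[, 3]
  )
  attr(out, "placement") <- placement
  attr(out, "fs") <- fs
  class(out) <- c("imu_recording", class(out))
  out
}

imu_channel_cols <- c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")

#' @rdname imu_recording
#' @param x an `imu_recording`.
#' @export
imu_sampling_rate <- function(x) {
  attr(x, "fs") %||% check_uniform_time(x$time_s)
}

#' @rdname imu_recording
#' @param path file path for the CSV.
#' @param units `"si"` (default) or `"native"`; `NULL` consults the
#'   `# units:` comment line if present, else assumes SI.
#' @export
read_imu_csv <- function(path, placement = "other", units = NULL) {
  if (!file.exists(path)) abort(sprintf("IMU file not found: %s", path))
  first <- readLines(path, n = 1)
  flagged <- NULL
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("units:\\s*(\\w+)", first))[[1]]
    if (length(m) == 2) flagged <- m[2]
  }
  units <- units %||% flagged %||% "si"
  units <- match.arg(units, c("si", "native"))
  dat <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("time_s", imu_channel_cols)
  missing <- setdiff(need, names(dat))
  if (length(missing) > 0) {
    abort(sprintf("IMU CSV is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  accel <- as.matrix(dat[c("ax", "ay", "az")])
  gyro <- as.matrix(dat[c("gx", "gy", "gz")])
  mag <- as.matrix(dat[c("mx", "my", "mz")])
  if (units == "native") {
    accel <- accel * 9.80665      # g -> m/s^2
    gyro <- gyro * pi / 180       # deg/s -> rad/s
    mag <- mag * 100              # Gauss -> microtesla
  }
  imu_recording(dat$time_s, accel, gyro, mag, placement = placement)
}

#' @rdname imu_recording
#' @export
write_imu_csv <- function(x, path) {
  stopifnot(inherits(x, "imu_recording") || all(c("time_s", imu_channel_cols) %in% names(x)))
  readr::write_csv(tibble::as_tibble(x)[c("time_s", imu_channel_cols)], path,
                   progress = FALSE)
  invisible(path)
}

# Zero-phase Butterworth with odd-reflection padding at both ends so that the
# startup transient of each pass decays inside the pad; exact DC gain 1.
butter_filtfilt <- function(x, fs, cutoff_hz, order) {
  n <- length(x)
  if (cutoff_hz >= fs / 2) {
    abort(sprintf("filter cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                  cutoff_hz, fs / 2))
  }
  if (n <= 3 * order) abort("signal too short for the requested filter order")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  npad <- min(n - 1, max(3L * as.integer(round(fs / cutoff_hz)), 12L * order))
  front <- 2 * x[1] - x[(npad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - npad)]
  xp <- c(front, x, back)
  # filter the deviation from the first sample: the zero-state transient then
  # scales with the local signal change, not its absolute level (exact at DC)
  run <- function(v) {
    as.numeric(signal::filter(bf, v - v[1])) + v[1] * sum(bf$b) / sum(bf$a)
  }
  y <- rev(run(rev(run(xp))))
  y[(npad + 1):(npad + n)]
}

#' Zero-phase low-pass Butterworth filter
#'
#' Smooths kinematic signals with a low-pass Butterworth filter applied
#' forward and backward (zero phase lag). The default 4th-order, 6 Hz design
#' is the standard choice for walking kinematics sampled at 200 Hz. `order`
#' is the designed order of each pass; the forward-backward application
#' doubles the effective order and moves the -3 dB point slightly below
#' `cutoff_hz` (the -6 dB point of a single pass).
#'
#' Zero-phase filtering matters here because the downstream continuous
#' relative phase analysis is a timing measure: a causal filter's group delay
#' would bias the hip-knee phase difference. Set `zero_phase = FALSE` for a
#' single causal forward pass.
#'
#' @param x an `imu_recording`, a joint-angle tibble (columns `hip_deg`,
#'   `knee_deg`), or a numeric vector.
#' @param cutoff_hz cutoff frequency in Hz (default 6).
#' @param order designed filter order per pass (default 4).
#' @param fs sampling rate in Hz; taken from `x` when it is a recording or a
#'   tibble with a `time_s` column.
#' @param zero_phase apply forward and backward (default `TRUE`).
#' @return object of the same type as `x` with every signal channel filtered;
#'   length is unchanged.
#' @export
lowpass_filter <- function(x, cutoff_hz = 6, order = 4, fs = NULL,
                           zero_phase = TRUE) {
  filt1 <- function(v, fs) {
    if (zero_phase) return(butter_filtfilt(v, fs, cutoff_hz, order))
    if (cutoff_hz >= fs / 2) {
      abort(sprintf("filter cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                    cutoff_hz, fs / 2))
    }
    bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
    as.numeric(signal::filter(bf, v))
  }
  if (is.numeric(x) && is.null(dim(x))) {
    if (is.null(fs)) abort("`fs` is required when filtering a bare numeric vector")
    return(filt1(x, fs))
  }
  if (is.data.frame(x)) {
    fs <- fs %||% attr(x, "fs") %||% check_uniform_time(x$time_s)
    cols <- intersect(c(imu_channel_cols, "hip_deg", "knee_deg", "shank_gyro_z"),
                      names(x))
    if (length(cols) == 0) abort("no recognised signal channels to filter")
    for (cl in cols) x[[cl]] <- filt1(x[[cl]], fs)
    return(x)
  }
  abort("unsupported input type for `lowpass_filter()`")
}
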