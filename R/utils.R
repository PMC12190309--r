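#' @importFrom rlang .data abort warn inform %||%
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Analytic signal via the frequency-domain construction: zero out negative
# frequencies, double positive ones, keep DC (and Nyquist for even n).
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 4) abort("signal too short for an analytic-signal construction")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Unwrap a phase sequence given in degrees.
unwrap_deg <- function(phi_deg) {
  signal::unwrap(phi_deg * pi / 180) * 180 / pi
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Uniform-sampling check: max deviation of successive dt from the median dt.
check_uniform_time <- function(time_s, tol = 0.01, what = "time") {
  dt <- diff(time_s)
  if (any(dt <= 0)) abort(sprintf("%s vector must be strictly increasing", what))
  if (max(abs(dt - stats::median(dt))) > tol * stats::median(dt)) {
    abort(sprintf("%s vector is not uniformly sampled (jitter > %g%%)", what, 100 * tol))
  }
  invisible(1 / stats::median(dt))
}

# Linear resampling of y (sampled at indices idx) onto 101 points spanning
# [from, to] inclusive. Index positions may be fractional.
resample_101 <- function(y, from, to) {
  pos <- seq(from, to, length.out = 101L)
  stats::approx(x = seq_along(y), y = y, xout = pos, rule = 2)$y
}
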