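#' Uniformly sampled time series
#'
#' Lightweight container for a uniformly sampled signal (position, velocity,
#' or angle). All signal-processing primitives in the package consume and
#' return `fall_series` objects.
#'
#' @param values Numeric vector of samples.
#' @param rate Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample in seconds.
#' @param unit Optional unit label (e.g. `"m"`, `"m/s"`, `"deg"`).
#' @return An object of class `fall_series`.
#' @examples
#' s <- fs_series(sin(2 * pi * 2 * seq(0, 1, by = 1 / 600)), rate = 600)
#' fs_duration(s)
#' @export
fs_series <- function(values, rate, start_time = 0, unit = NULL) {
  stopifnot(is.numeric(values), length(rate) == 1L, rate > 0)
  structure(
    list(values = as.numeric(values), rate = as.numeric(rate),
         start_time = as.numeric(start_time), unit = unit),
    class = "fall_series"
  )
}

#' @export
print.fall_series <- function(x, ...) {
  cat(sprintf("<fall_series: %d samples @ %g Hz, t0 = %g s%s>\n",
              length(x$values), x$rate, x$start_time,
              if (!is.null(x$unit)) paste0(", ", x$unit) else ""))
  invisible(x)
}

#' @rdname fs_series
#' @param s A `fall_series`.
#' @export
fs_time <- function(s) {
  s$start_time + (seq_along(s$values) - 1L) / s$rate
}

#' @rdname fs_series
#' @export
fs_duration <- function(s) (length(s$values) - 1L) / s$rate

as_series <- function(x, rate, start_time = 0) {
  if (inherits(x, "fall_series")) x else fs_series(x, rate, start_time)
}

#' Zero-phase dual-pass Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass filter forward and backward (dual pass),
#' giving zero phase lag and a squared magnitude response: at the cutoff
#' frequency the gain is exactly 1/2 (the single pass contributes
#' \eqn{|H|^2 = 1/2} there). Transients are suppressed by odd-reflection
#' padding at both ends, discarded after filtering. No cutoff pre-warping is
#' applied to compensate the two passes, matching common biomechanics
#' practice.
#'
#' @param s A [fs_series()] (or numeric vector with `rate` supplied).
#' @param cutoff Cutoff frequency in Hz; must be below the Nyquist rate.
#' @param order Filter order of each pass (default 4).
#' @param rate Sampling rate, only used when `s` is a bare numeric vector.
#' @return A `fall_series` of the same length and rate.
#' @examples
#' s <- fs_series(rnorm(300), rate = 30)
#' f <- lowpass_dualpass(s, cutoff = 10)
#' @export
lowpass_dualpass <- function(s, cutoff, order = 4L, rate = NULL) {
  s <- as_series(s, rate)
  n <- length(s$values)
  if (cutoff <= 0 || cutoff >= s$rate / 2) {
    stop("cutoff must lie in (0, rate/2); got ", cutoff, " Hz at rate ",
         s$rate, " Hz")
  }
  # pad long enough to absorb the IIR startup transient, whose length
  # scales with rate/cutoff, not just with the filter order
  pad <- min(n - 1L, max(3L * (order + 1L), ceiling(3 * s$rate / cutoff)))
  if (n <= 3L * order) {
    stop("series too short for order-", order, " dual-pass filtering (n = ",
         n, ")")
  }
  bf <- signal::butter(order, cutoff / (s$rate / 2), type = "low")
  x <- s$values
  # odd reflection about the end values keeps level and slope continuous
  left <- 2 * x[1L] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(left, x, right)
  # level-shift before each pass so a constant input is reproduced exactly
  # (removes the DC step transient of zero initial filter state)
  y <- signal::filter(bf, xp - xp[1L]) + xp[1L]
  y <- rev(y)
  y <- signal::filter(bf, y - y[1L]) + y[1L]
  y <- rev(y)
  out <- y[(pad + 1L):(pad + n)]
  fs_series(as.numeric(out), s$rate, s$start_time, s$unit)
}

#' Resample a series to a new rate
#'
#' Cubic-spline interpolation of positions (so that differentiated
#' velocities remain continuous); set `method = "linear"` for piecewise
#' linear interpolation. The duration is preserved, and when the target rate
#' is an integer multiple of the source rate the original sample instants
#' are reproduced exactly.
#'
#' @param s A [fs_series()].
#' @param target_rate New sampling rate in Hz.
#' @param method `"spline"` (default) or `"linear"`.
#' @return A `fall_series` at `target_rate`.
#' @export
resample_to <- function(s, target_rate, method = c("spline", "linear")) {
  method <- match.arg(method)
  stopifnot(inherits(s, "fall_series"), target_rate > 0)
  if (isTRUE(all.equal(target_rate, s$rate))) return(s)
  t_old <- fs_time(s)
  n_new <- floor(fs_duration(s) * target_rate + 1e-9) + 1L
  t_new <- s$start_time + (seq_len(n_new) - 1L) / target_rate
  v <- if (method == "spline") {
    stats::spline(t_old, s$values, xout = t_new, method = "fmm")$y
  } else {
    stats::approx(t_old, s$values, xout = t_new, rule = 2)$y
  }
  fs_series(v, target_rate, s$start_time, s$unit)
}

#' Synchronization lag by normalized cross-correlation
#'
#' Finds the lag (in seconds) that maximizes the normalized
#' cross-correlation between a reference and a test series sampled at a
#' common rate, searching integer sample shifts within `max_lag`. A positive
#' lag means the test series is delayed relative to the reference; shifting
#' the test by `-lag` aligns the two. Ties are broken toward the smaller
#' absolute lag. The overlap after any candidate shift must cover at least
#' half of the shorter series.
#'
#' @param reference,test [fs_series()] objects at the same rate.
#' @param max_lag Maximum absolute lag to search, seconds (default 2).
#' @return Lag in seconds (multiple of `1/rate`).
#' @export
sync_lag <- function(reference, test, max_lag = 2) {
  stopifnot(inherits(reference, "fall_series"), inherits(test, "fall_series"))
  if (abs(reference$rate - test$rate) > 1e-9) {
    stop("series must share a sampling rate; resample first")
  }
  r <- reference$values
  x <- test$values
  if (stats::sd(r) == 0 || stats::sd(x) == 0) {
    stop("zero-variance input: correlation undefined")
  }
  lmax <- as.integer(round(max_lag * reference$rate))
  min_overlap <- ceiling(min(length(r), length(x)) / 2)
  best <- c(corr = -Inf, lag = 0L)
  for (k in seq(-lmax, lmax)) {
    # candidate: test delayed by k samples, i.e. x[i + k] ~ r[i]
    lo <- max(1L, 1L - k)
    hi <- min(length(r), length(x) - k)
    if (hi - lo + 1L < min_overlap) next
    ir <- lo:hi
    # window-local centering (Pearson): immune to partial-overlap bias
    rc <- r[ir] - mean(r[ir])
    xc <- x[ir + k] - mean(x[ir + k])
    den <- sqrt(sum(rc^2) * sum(xc^2))
    if (den == 0) next
    cc <- sum(rc * xc) / den
    if (cc > best[["corr"]] + 1e-12 ||
        (abs(cc - best[["corr"]]) <= 1e-12 && abs(k) < abs(best[["lag"]]))) {
      best <- c(corr = cc, lag = k)
    }
  }
  if (!is.finite(best[["corr"]])) stop("no admissible overlap within max_lag")
  best[["lag"]] / reference$rate
}

#' First-order central-difference differentiation
#'
#' Interior samples use `(x[i+1] - x[i-1]) / (2 dt)`; the endpoints use
#' one-sided differences so the output has the same length as the input.
#'
#' @param s A [fs_series()] of positions (or angles).
#' @return A `fall_series` of velocities at the same rate.
#' @export
central_difference <- function(s) {
  stopifnot(inherits(s, "fall_series"))
  x <- s$values
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples for central differences")
  dt <- 1 / s$rate
  v <- numeric(n)
  v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  v[1L] <- (x[2L] - x[1L]) / dt
  v[n] <- (x[n] - x[n - 1L]) / dt
  unit <- if (!is.null(s$unit)) paste0(s$unit, "/s") else NULL
  fs_series(v, s$rate, s$start_time, unit)
}

#' Fraction of spectral energy above a frequency
#'
#' Fraction of the total spectral energy (squared DFT magnitude, DC bin
#' excluded) carried by frequencies strictly above `f`. Used to screen
#' ground-truth traces: physiological fall movement concentrates below
#' 10 Hz, so raw motion-capture traces should carry only a small share of
#' their energy above 20 Hz.
#'
#' @param s A [fs_series()].
#' @param f Threshold frequency in Hz.
#' @return Fraction in \[0, 1\]. If `f` is at or above the Nyquist rate the
#'   function warns and returns 0.
#' @export
energy_fraction_above <- function(s, f) {
  stopifnot(inherits(s, "fall_series"))
  n <- length(s$values)
  if (n < 8L) stop("need at least 8 samples for a spectral estimate")
  if (f >= s$rate / 2) {
    warning("threshold at or above Nyquist; returning 0")
    return(0)
  }
  sp <- Mod(stats::fft(s$values))^2
  freqs <- (seq_len(n) - 1L) * s$rate / n
  freqs <- pmin(freqs, s$rate - freqs)  # fold to [0, rate/2]
  keep <- seq_len(n)[-1L]               # exclude DC
  total <- sum(sp[keep])
  if (total == 0) return(0)
  sum(sp[keep][freqs[keep] > f]) / total
}
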