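series_window <- function(s, interval) {
  v <- if (inherits(s, "fall_series")) s$values else s
  if (is.null(interval)) return(v)
  a <- as.integer(interval[1]) + 1L
  b <- as.integer(interval[2])
  if (a > b || a < 1L || b > length(v)) stop("interval outside series")
  v[a:b]
}

#' Root mean square error between two aligned signals
#'
#' RMSE over the fall interval between a test signal and the ground-truth
#' reference, both at a common rate and alignment.
#'
#' @param test,ref [fs_series()] objects or numeric vectors of equal
#'   length over the interval.
#' @param interval 0-based half-open frame range `c(start, end)`; `NULL`
#'   uses the full overlap.
#' @return Non-negative RMSE in the signals' units.
#' @export
rmse <- function(test, ref, interval = NULL) {
  x <- series_window(test, interval)
  r <- series_window(ref, interval)
  if (length(x) != length(r)) {
    stop("test and reference have different lengths after alignment (",
         length(x), " vs ", length(r), ")")
  }
  sqrt(mean((x - r)^2))
}

#' Normalized RMSE (percent of reference amplitude)
#'
#' RMSE expressed as a percentage of the reference signal's amplitude,
#' where amplitude is the peak-to-peak range of the reference over the fall
#' interval. This normalization scales every NRMSE the package reports.
#'
#' @inheritParams rmse
#' @return NRMSE in percent.
#' @export
nrmse <- function(test, ref, interval = NULL) {
  r <- series_window(ref, interval)
  amp <- max(r) - min(r)
  if (amp <= 0) stop("zero-amplitude reference: normalization undefined")
  100 * rmse(test, ref, interval) / amp
}

#' Raw and percent difference in peak velocity
#'
#' Signed difference between the test and reference peak velocities (peak =
#' maximal magnitude with sign preserved, within the fall interval):
#' `raw = peak(test) - peak(ref)`, `percent = 100 * raw / |peak(ref)|`.
#' Positive values mean the test overestimates. Absolute variants are
#' included.
#'
#' @param test,ref [fs_series()] velocity series at a common rate.
#' @param interval 0-based half-open frame range.
#' @return List with `raw`, `percent`, `abs_raw`, `abs_percent`,
#'   `peak_test`, `peak_ref`.
#' @export
peak_difference <- function(test, ref, interval = NULL) {
  pt <- peak_velocity(as_series(test, ref$rate), interval)$peak_value
  pr <- peak_velocity(ref, interval)$peak_value
  if (pr == 0) stop("zero reference peak")
  raw <- pt - pr
  pct <- 100 * raw / abs(pr)
  list(raw = raw, percent = pct, abs_raw = abs(raw), abs_percent = abs(pct),
       peak_test = pt, peak_ref = pr)
}

#' Linear agreement between paired peak values
#'
#' Ordinary least-squares fit of test peaks on reference peaks, summarizing
#' agreement by slope, intercept, R-squared, and the mean signed error in
#' percent of the reference magnitude.
#'
#' @param test_peaks,ref_peaks Numeric vectors of paired peaks (n >= 3).
#' @return List with `slope`, `intercept`, `r_squared`,
#'   `mean_signed_error_pct`, `n`.
#' @export
linear_agreement <- function(test_peaks, ref_peaks) {
  stopifnot(length(test_peaks) == length(ref_peaks), length(ref_peaks) >= 3)
  if (stats::sd(ref_peaks) == 0) stop("zero variance in reference peaks")
  fit <- stats::lm(test_peaks ~ ref_peaks)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((test_peaks - mean(test_peaks))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       mean_signed_error_pct =
         mean(100 * (test_peaks - ref_peaks) / abs(ref_peaks)),
       n = length(ref_peaks))
}

#' Aggregate accuracy records into mean +/- SE tables
#'
#' Groups a tidy accuracy-record table and reports, per group and metric
#' column, the mean, standard error (SD/sqrt(n)), and n. Percent measures
#' are expected to be computed per fall before this averaging (the package's
#' comparison functions do so). A single-record group reports SE = 0 and is
#' flagged via `n = 1`.
#'
#' @param records Data frame of accuracy records (e.g. from
#'   [compare_signal_sets()]).
#' @param group_by Character vector of grouping column names.
#' @param metrics Metric columns to aggregate; defaults to all numeric
#'   non-grouping columns.
#' @return Data frame with one row per group and `<metric>_mean`,
#'   `<metric>_se` columns plus `n`.
#' @export
aggregate_accuracy <- function(records, group_by,
                               metrics = NULL) {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            all(group_by %in% names(records)))
  if (is.null(metrics)) {
    metrics <- names(records)[vapply(records, is.numeric, logical(1))]
    metrics <- setdiff(metrics, group_by)
  }
  key <- interaction(records[group_by], drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(key), function(lv) {
    sub <- records[key == lv, , drop = FALSE]
    out <- sub[1, group_by, drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]][!is.na(sub[[m]])]
      out[[paste0(m, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0(m, "_se")]] <- if (length(v) > 1) {
        stats::sd(v) / sqrt(length(v))
      } else 0
    }
    out$n <- nrow(sub)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
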