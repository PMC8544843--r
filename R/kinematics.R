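#' Zero position series at fall initiation
#'
#' Subtracts from every horizontal and vertical position series its value at
#' the fall-initiation frame, so all positions are expressed as
#' displacements from the start of the fall. This removes constant offsets
#' between the origins of the motion-capture and video coordinate systems.
#'
#' @param markers Named list of `n x k` marker matrices (k = 2 or 3).
#' @param start_frame 0-based frame index of fall initiation.
#' @param cols Columns to zero; defaults to all.
#' @return The marker list with zeroed columns.
#' @export
zero_initial <- function(markers, start_frame, cols = NULL) {
  stopifnot(length(markers) > 0)
  i <- as.integer(start_frame) + 1L
  lapply(markers, function(m) {
    j <- if (is.null(cols)) seq_len(ncol(m)) else cols
    m[, j] <- sweep(m[, j, drop = FALSE], 2L, m[i, j], "-")
    m
  })
}

unwrap_deg <- function(theta) {
  d <- diff(theta)
  jump <- round(d / 360)
  theta - c(0, cumsum(jump)) * 360
}

#' Absolute segment angle series
#'
#' Angle of the distal-minus-proximal segment vector with respect to the
#' horizontal, computed with the two-argument inverse tangent in degrees and
#' unwrapped so the series is continuous (no inter-sample jump above 180
#' degrees) through rotations beyond +/-90 degrees.
#'
#' @param prox,dist `n x 2` matrices of (horizontal, vertical) positions of
#'   the proximal and distal markers, equal lengths and rates.
#' @param rate Sampling rate in Hz.
#' @param segment_name Label carried on the result.
#' @return A [fs_series()] of angles in degrees (class also
#'   `angle_series`), with the segment name attached.
#' @export
segment_angle_series <- function(prox, dist, rate, segment_name = "segment") {
  stopifnot(nrow(prox) == nrow(dist), ncol(prox) == 2L, ncol(dist) == 2L)
  dh <- dist[, 1L] - prox[, 1L]
  dv <- dist[, 2L] - prox[, 2L]
  zero <- which(dh == 0 & dv == 0)
  if (length(zero)) {
    stop("undefined angle: proximal and distal markers coincide at frame ",
         zero[1] - 1L, " (segment ", segment_name, ")")
  }
  theta <- unwrap_deg(atan2(dv, dh) * 180 / pi)
  s <- fs_series(theta, rate, unit = "deg")
  s$segment <- segment_name
  class(s) <- c("angle_series", class(s))
  s
}

#' Peak velocity within an interval
#'
#' Value of maximal velocity magnitude within the fall interval, with the
#' sign of the underlying sample preserved, plus the time at which it
#' occurs. (A signed-maximum mode is available via `criterion`.)
#'
#' @param v A [fs_series()] of velocities.
#' @param interval 0-based half-open frame range `c(start, end)` within the
#'   series; default the whole series.
#' @param criterion `"magnitude"` (default): sample with largest `|v|`;
#'   `"signed"`: largest signed value.
#' @return List with `peak_value` (signed), `peak_time` (s), `peak_frame`
#'   (0-based).
#' @export
peak_velocity <- function(v, interval = NULL,
                          criterion = c("magnitude", "signed")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(v, "fall_series"))
  n <- length(v$values)
  if (is.null(interval)) interval <- c(0L, n)
  a <- as.integer(interval[1]) + 1L
  b <- as.integer(interval[2])
  if (a > b || a < 1L || b > n) stop("empty or out-of-range interval")
  seg <- v$values[a:b]
  idx <- if (criterion == "magnitude") which.max(abs(seg)) else which.max(seg)
  frame <- a + idx - 2L
  list(peak_value = seg[idx],
       peak_time = v$start_time + frame / v$rate,
       peak_frame = frame)
}

#' Out-of-plane movement summary
#'
#' Peak absolute out-of-plane (Y) displacement from its fall-initiation
#' value, and peak absolute out-of-plane velocity (central difference), per
#' marker, within the fall interval. Out-of-plane movement is invisible to
#' a single camera perpendicular to the fall plane and is the dominant
#' error source for limb kinematics in sideways falls.
#'
#' @param trial A [trial3d()].
#' @param interval 0-based half-open frame range; default the trial's fall
#'   interval.
#' @return Data frame with columns `marker`, `peak_displacement_m`,
#'   `peak_velocity_ms`.
#' @export
out_of_plane_summary <- function(trial, interval = NULL) {
  stopifnot(inherits(trial, "trial3d"))
  if (is.null(interval)) interval <- fall_interval(trial)
  a <- interval[1] + 1L
  b <- interval[2]
  rate <- trial$meta$sample_rate
  rows <- lapply(names(trial$markers), function(mk) {
    y <- trial$markers[[mk]][, "Y"]
    y0 <- y - y[a]
    vy <- central_difference(fs_series(y0, rate))$values
    data.frame(marker = mk,
               peak_displacement_m = max(abs(y0[a:b])),
               peak_velocity_ms = max(abs(vy[a:b])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' In-plane versus resultant horizontal displacement
#'
#' Returns, per marker, the zeroed in-plane horizontal displacement (X) and
#' the resultant horizontal displacement `sqrt(dX^2 + dY^2)` that also
#' counts out-of-plane motion. The resultant is pointwise at least `|X|`.
#'
#' @param trial A [trial3d()].
#' @return Named list per marker of `n x 2` matrices with columns
#'   `x_inplane`, `resultant_xy`.
#' @export
resultant_xy <- function(trial) {
  stopifnot(inherits(trial, "trial3d"))
  i <- trial$meta$fall_start_frame + 1L
  lapply(trial$markers, function(m) {
    dx <- m[, "X"] - m[i, "X"]
    dy <- m[, "Y"] - m[i, "Y"]
    cbind(x_inplane = dx, resultant_xy = sqrt(dx^2 + dy^2))
  })
}
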