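#' Trial metadata
#'
#' Per-fall metadata shared by the 3D (motion-capture) and 2D (video) sides.
#' Frame indices are 0-based and the fall interval is the half-open range
#' `[fall_start_frame, fall_end_frame)` at `sample_rate`.
#'
#' @param trial_id Character identifier.
#' @param direction One of `"forward"`, `"backward"`, `"sideways"`.
#' @param initiation One of `"perturbation"` (translating-platform induced)
#'   or `"self_initiated"` (incorrect weight shifting).
#' @param participant_height Standing height in metres, in (1, 2.5).
#' @param fall_start_frame,fall_end_frame 0-based frame indices of fall
#'   initiation and end of fall (cessation of movement).
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `trial_meta`.
#' @export
trial_meta <- function(trial_id, direction, initiation, participant_height,
                       fall_start_frame, fall_end_frame, sample_rate) {
  direction <- match.arg(direction, c("forward", "backward", "sideways"))
  initiation <- match.arg(initiation, c("perturbation", "self_initiated"))
  stopifnot(participant_height > 1.0, participant_height < 2.5,
            sample_rate > 0)
  fall_start_frame <- as.integer(fall_start_frame)
  fall_end_frame <- as.integer(fall_end_frame)
  if (!(fall_start_frame < fall_end_frame)) {
    stop("fall_start_frame must precede fall_end_frame")
  }
  structure(
    list(trial_id = as.character(trial_id), direction = direction,
         initiation = initiation,
         participant_height = as.numeric(participant_height),
         fall_start_frame = fall_start_frame,
         fall_end_frame = fall_end_frame,
         sample_rate = as.numeric(sample_rate)),
    class = "trial_meta"
  )
}

#' Canonical marker vocabulary
#'
#' Marker labels used throughout the package. The pelvis is tracked at the
#' greater trochanter (`GT`) in forward/backward falls and at the anterior
#' superior iliac spine (`ASIS`) in sideways falls.
#'
#' @return Character vector of canonical labels.
#' @export
marker_vocabulary <- function() {
  c("head", "shoulder", "sternum", "elbow", "wrist", "GT", "ASIS",
    "knee", "ankle")
}

.marker_synonyms <- c(
  head = "head", helmet = "head",
  shoulder = "shoulder", acromion = "shoulder",
  sternum = "sternum", manubrium = "sternum",
  elbow = "elbow", humeral_epicondyle = "elbow",
  wrist = "wrist", radial_styloid = "wrist",
  gt = "GT", greater_trochanter = "GT", trochanter = "GT",
  asis = "ASIS",
  knee = "knee", femoral_condyle = "knee",
  ankle = "ankle", malleolus = "ankle"
)

#' Normalize a marker label to the canonical vocabulary
#'
#' Case-insensitive and idempotent over the canonical vocabulary; common
#' anatomical synonyms (e.g. `"acromion"`, `"greater_trochanter"`) are
#' mapped. Unknown labels raise an error rather than being dropped.
#'
#' @param label Character vector of labels.
#' @return Character vector of canonical labels.
#' @export
normalize_marker_label <- function(label) {
  key <- gsub("[ .-]+", "_", tolower(trimws(label)))
  out <- unname(.marker_synonyms[key])
  if (anyNA(out)) {
    stop("unknown marker label(s): ",
         paste(unique(label[is.na(out)]), collapse = ", "))
  }
  out
}

check_marker_matrix <- function(markers, ncol_expected, what) {
  stopifnot(is.list(markers), length(markers) > 0,
            !is.null(names(markers)))
  lens <- vapply(markers, nrow, integer(1))
  if (length(unique(lens)) != 1L) {
    stop(what, ": all marker series must share one length")
  }
  ok <- vapply(markers, function(m) is.matrix(m) && ncol(m) == ncol_expected,
               logical(1))
  if (!all(ok)) {
    stop(what, ": each marker must be a matrix with ", ncol_expected,
         " columns")
  }
  invisible(lens[[1L]])
}

#' 3D motion-capture trial
#'
#' One fall's 3D marker trajectories (nominally 600 Hz). Coordinate
#' convention: X is horizontal in the plane of the fall, Y is horizontal
#' perpendicular to the plane of the fall (out-of-plane, positive toward
#' the 90-degree camera), Z is vertical (up positive), all in metres.
#'
#' @param meta A [trial_meta()].
#' @param markers Named list of `n x 3` matrices (columns X, Y, Z), one per
#'   canonical marker label; all the same number of rows.
#' @return An object of class `trial3d`.
#' @export
trial3d <- function(meta, markers) {
  stopifnot(inherits(meta, "trial_meta"))
  names(markers) <- normalize_marker_label(names(markers))
  n <- check_marker_matrix(markers, 3L, "trial3d")
  markers <- lapply(markers, function(m) {
    colnames(m) <- c("X", "Y", "Z"); m
  })
  if (meta$fall_end_frame > n) stop("fall_end_frame beyond series length")
  structure(list(meta = meta, markers = markers, n_frames = n),
            class = "trial3d")
}

#' 2D digitized video trial
#'
#' One fall's planar marker trajectories from a single camera view at 30 Hz,
#' either in pixels (image coordinates, origin top-left, vertical axis down)
#' awaiting calibration, or in metres (horizontal, vertical-up) after
#' calibration.
#'
#' @param meta A [trial_meta()] (with `sample_rate` = video frame rate).
#' @param markers Named list of `n x 2` matrices (columns h, v).
#' @param camera_angle Camera angle to the fall plane, degrees (30/60/90).
#' @param unit `"pixel"` or `"metre"`.
#' @param resolution Image resolution in pixels, default `c(640, 480)`.
#' @param flags Optional named list of per-marker logical vectors (e.g.
#'   out-of-frame flags from the simulated observer).
#' @return An object of class `trial2d`.
#' @export
trial2d <- function(meta, markers, camera_angle, unit = c("pixel", "metre"),
                    resolution = c(640, 480), flags = NULL) {
  stopifnot(inherits(meta, "trial_meta"))
  unit <- match.arg(unit)
  names(markers) <- normalize_marker_label(names(markers))
  n <- check_marker_matrix(markers, 2L, "trial2d")
  markers <- lapply(markers, function(m) {
    colnames(m) <- c("h", "v"); m
  })
  structure(list(meta = meta, markers = markers,
                 camera_angle = as.numeric(camera_angle), unit = unit,
                 resolution = resolution, flags = flags, n_frames = n),
            class = "trial2d")
}

#' @export
print.trial3d <- function(x, ...) {
  cat(sprintf("<trial3d %s: %s/%s, %d markers x %d frames @ %g Hz, fall [%d, %d)>\n",
              x$meta$trial_id, x$meta$direction, x$meta$initiation,
              length(x$markers), x$n_frames, x$meta$sample_rate,
              x$meta$fall_start_frame, x$meta$fall_end_frame))
  invisible(x)
}

#' @export
print.trial2d <- function(x, ...) {
  cat(sprintf("<trial2d %s: %g deg view, %s units, %d markers x %d frames @ %g Hz>\n",
              x$meta$trial_id, x$camera_angle, x$unit, length(x$markers),
              x$n_frames, x$meta$sample_rate))
  invisible(x)
}

#' Direction-specific segment definitions
#'
#' Proximal/distal marker pairs defining the absolute angles of six body
#' segments. The head segment uses head and shoulder markers in forward and
#' backward falls, and head and sternum markers in sideways falls; the
#' pelvis landmark is the greater trochanter (GT) fore-aft and the ASIS in
#' sideways falls.
#'
#' @param direction Fall direction.
#' @return Data frame with columns `segment`, `proximal`, `distal`.
#' @export
segment_map <- function(direction = c("forward", "backward", "sideways")) {
  direction <- match.arg(direction)
  pelvis <- if (direction == "sideways") "ASIS" else "GT"
  head_prox <- if (direction == "sideways") "sternum" else "shoulder"
  data.frame(
    segment = c("head", "torso", "thigh", "upper_arm", "forearm", "shank"),
    proximal = c(head_prox, pelvis, pelvis, "shoulder", "elbow", "knee"),
    distal = c("head", "shoulder", "knee", "elbow", "wrist", "ankle"),
    stringsAsFactors = FALSE
  )
}

#' Fall interval of a trial
#'
#' @param trial A `trial3d` or `trial2d`.
#' @return Integer vector `c(start, end)` of 0-based half-open frame range.
#' @export
fall_interval <- function(trial) {
  c(trial$meta$fall_start_frame, trial$meta$fall_end_frame)
}
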