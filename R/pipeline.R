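#' Build ground-truth signal sets from 3D trials
#'
#' Constructs the reference ("Q20") side of every comparison: 3D positions
#' are low-pass filtered with the dual-pass 4th-order Butterworth at the
#' ground-truth cutoff (20 Hz), velocities are formed by central
#' differences at the full rate, absolute segment angles are computed from
#' the direction-specific marker pairs, and linear positions are zeroed at
#' fall initiation. A QC report gives, per unfiltered vertical-velocity
#' trace, the fraction of spectral energy above the cutoff and the overall
#' share of traces under the 4% criterion.
#'
#' @param trials List of [trial3d()] objects (or a single trial).
#' @param cutoff Ground-truth cutoff frequency, Hz (default 20).
#' @return List with `sets` (named list of signal sets) and `qc` (list with
#'   per-trace data frame `traces` and `share_under_4pct`).
#' @export
build_ground_truth <- function(trials, cutoff = 20) {
  if (inherits(trials, "trial3d")) trials <- list(trials)
  qc_rows <- list()
  sets <- lapply(trials, function(tr) {
    rate <- tr$meta$sample_rate
    for (mk in names(tr$markers)) {
      raw_vv <- central_difference(fs_series(tr$markers[[mk]][, "Z"], rate))
      qc_rows[[length(qc_rows) + 1L]] <<- data.frame(
        trial_id = tr$meta$trial_id, marker = mk,
        energy_above = energy_fraction_above(raw_vv, cutoff),
        stringsAsFactors = FALSE)
    }
    filtered <- lapply(tr$markers, function(m) {
      cbind(h = lowpass_dualpass(fs_series(m[, "X"], rate), cutoff)$values,
            v = lowpass_dualpass(fs_series(m[, "Z"], rate), cutoff)$values)
    })
    make_signal_set(filtered, tr$meta, rate, fall_interval(tr))
  })
  names(sets) <- vapply(trials, function(t) t$meta$trial_id, character(1))
  qc <- do.call(rbind, qc_rows)
  list(sets = sets,
       qc = list(traces = qc,
                 share_under_4pct = mean(qc$energy_above < 0.04),
                 n = nrow(qc)))
}

# Assemble zeroed positions, velocities, and segment angles from calibrated
# planar (h, v) marker matrices.
make_signal_set <- function(markers_hv, meta, rate, interval) {
  start <- interval[1]
  pos <- zero_initial(markers_hv, start)
  vel <- lapply(markers_hv, function(m) {
    cbind(h = central_difference(fs_series(m[, "h"], rate))$values,
          v = central_difference(fs_series(m[, "v"], rate))$values)
  })
  smap <- segment_map(meta$direction)
  ang <- list()
  angvel <- list()
  for (i in seq_len(nrow(smap))) {
    pr <- smap$proximal[i]
    di <- smap$distal[i]
    if (!(pr %in% names(markers_hv)) || !(di %in% names(markers_hv))) next
    a <- segment_angle_series(markers_hv[[pr]], markers_hv[[di]], rate,
                              smap$segment[i])
    ang[[smap$segment[i]]] <- a$values
    angvel[[smap$segment[i]]] <- central_difference(a)$values
  }
  structure(list(trial_id = meta$trial_id, direction = meta$direction,
                 rate = rate, interval = interval, pos = pos, vel = vel,
                 ang = ang, angvel = angvel),
            class = "signal_set")
}

#' Process a test-side trial against a ground-truth signal set
#'
#' Runs the video-side (or alternative motion-capture-side) processing
#' chain: calibrate pixels to metres (2D pixel trials only), low-pass
#' filter positions at the test cutoff at the native rate, upsample to the
#' ground-truth rate by cubic splines, synchronize to the ground truth by
#' cross-correlation of head vertical velocity, zero at fall initiation,
#' and derive velocities and segment angles — yielding a signal set aligned
#' sample-by-sample with the ground truth.
#'
#' @param trial A [trial2d()] (pixel or metre units) or [trial3d()].
#' @param ground_truth The matching trial's ground-truth signal set (one
#'   element of `build_ground_truth()$sets`).
#' @param cutoff Test-side low-pass cutoff, Hz.
#' @param calibration A `calibration_mapping`, required for pixel-unit 2D
#'   trials.
#' @param max_lag Synchronization search half-width, seconds.
#' @return A signal set aligned with `ground_truth`.
#' @export
process_test_side <- function(trial, ground_truth, cutoff,
                              calibration = NULL, max_lag = 0.5) {
  stopifnot(inherits(ground_truth, "signal_set"))
  if (inherits(trial, "trial2d") && trial$unit == "pixel") {
    if (is.null(calibration)) {
      stop("pixel-unit 2D trial requires a calibration mapping")
    }
    trial <- apply_calibration(calibration, trial)
  }
  markers_hv <- if (inherits(trial, "trial3d")) {
    lapply(trial$markers, function(m) cbind(h = m[, "X"], v = m[, "Z"]))
  } else {
    trial$markers
  }
  if (!("head" %in% names(markers_hv))) {
    stop("cannot synchronize: head marker missing")
  }
  rate <- trial$meta$sample_rate
  gt_rate <- ground_truth$rate
  up <- lapply(markers_hv, function(m) {
    fh <- lowpass_dualpass(fs_series(m[, "h"], rate), cutoff)
    fv <- lowpass_dualpass(fs_series(m[, "v"], rate), cutoff)
    cbind(h = resample_to(fh, gt_rate)$values,
          v = resample_to(fv, gt_rate)$values)
  })
  # synchronize on head vertical velocity
  gt_head_vv <- fs_series(ground_truth$vel$head[, "v"], gt_rate)
  test_head_vv <- central_difference(fs_series(up$head[, "v"], gt_rate))
  lag <- sync_lag(gt_head_vv, test_head_vv, max_lag = max_lag)
  k <- as.integer(round(lag * gt_rate))
  n_gt <- nrow(ground_truth$pos$head)
  aligned <- lapply(up, function(m) {
    idx <- seq_len(n_gt) + k
    out <- matrix(NA_real_, n_gt, 2L, dimnames = list(NULL, c("h", "v")))
    ok <- idx >= 1L & idx <= nrow(m)
    out[ok, ] <- m[idx[ok], ]
    # hold first/last observed sample at the borders
    if (any(!ok)) {
      first <- which(ok)[1]
      last <- rev(which(ok))[1]
      if (is.na(first)) stop("no overlap with ground truth after sync")
      out[seq_len(first - 1L), ] <- rep(out[first, ], each = first - 1L)
      if (last < n_gt) {
        out[(last + 1L):n_gt, ] <- rep(out[last, ], each = n_gt - last)
      }
    }
    out
  })
  set <- make_signal_set(aligned, trial$meta, gt_rate, ground_truth$interval)
  set$trial_id <- ground_truth$trial_id
  set$sync_lag_s <- lag
  set
}

outcome_units <- c(pos_v = "m", pos_h = "m", pos_ang = "deg",
                   vel_v = "m/s", vel_h = "m/s", vel_ang = "deg/s")

#' Compare a test signal set to its ground truth
#'
#' Produces one tidy accuracy record per body part (or segment) and
#' outcome: RMSE, NRMSE (% of the ground-truth peak-to-peak amplitude over
#' the fall interval), and — for velocity outcomes — the signed raw and
#' percent differences in peak velocity. The signed convention is
#' test minus reference, positive = overestimate.
#'
#' @param test_set Signal set from [process_test_side()].
#' @param gt_set Ground-truth signal set.
#' @return Data frame with columns `trial_id`, `direction`, `body_part`,
#'   `outcome`, `rmse`, `nrmse`, `peak_diff_raw`, `peak_diff_pct`.
#' @export
compare_signal_sets <- function(test_set, gt_set) {
  stopifnot(inherits(test_set, "signal_set"), inherits(gt_set, "signal_set"))
  iv <- gt_set$interval
  rate <- gt_set$rate
  rows <- list()
  add <- function(part, outcome, test_v, ref_v, is_velocity) {
    pr <- NA_real_
    pp <- NA_real_
    if (is_velocity) {
      pd <- peak_difference(fs_series(test_v, rate), fs_series(ref_v, rate),
                            iv)
      pr <- pd$raw
      pp <- pd$percent
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      trial_id = gt_set$trial_id, direction = gt_set$direction,
      body_part = part, outcome = outcome,
      rmse = rmse(test_v, ref_v, iv), nrmse = nrmse(test_v, ref_v, iv),
      peak_diff_raw = pr, peak_diff_pct = pp, stringsAsFactors = FALSE)
  }
  for (mk in intersect(names(test_set$pos), names(gt_set$pos))) {
    add(mk, "pos_h", test_set$pos[[mk]][, "h"], gt_set$pos[[mk]][, "h"], FALSE)
    add(mk, "pos_v", test_set$pos[[mk]][, "v"], gt_set$pos[[mk]][, "v"], FALSE)
    add(mk, "vel_h", test_set$vel[[mk]][, "h"], gt_set$vel[[mk]][, "h"], TRUE)
    add(mk, "vel_v", test_set$vel[[mk]][, "v"], gt_set$vel[[mk]][, "v"], TRUE)
  }
  for (sg in intersect(names(test_set$ang), names(gt_set$ang))) {
    add(sg, "pos_ang", test_set$ang[[sg]], gt_set$ang[[sg]], FALSE)
    add(sg, "vel_ang", test_set$angvel[[sg]], gt_set$angvel[[sg]], TRUE)
  }
  do.call(rbind, rows)
}

#' Simulated video observation plus calibration
#'
#' Convenience wrapper producing the calibrated (metre-unit) video-side
#' trial for one fall: positions the camera, images the calibration aid
#' (grid, possibly translated/rotated, or the participant's standing height
#' line, possibly with a height error), observes the fall with seeded pixel
#' noise, and applies the fitted calibration.
#'
#' @param trial A [trial3d()].
#' @param camera_angle Camera angle to the fall plane (30/60/90 degrees).
#' @param calibration `"grid2d"` or `"line1d"`.
#' @param grid_translation,grid_rotation Grid perturbations (m toward the
#'   camera / degrees about vertical).
#' @param height_error Error added to the participant height used for 1D
#'   calibration, metres.
#' @param noise_px Digitization noise, pixels (applied to fall markers and
#'   calibration features alike).
#' @param seed Seed for all noise draws.
#' @param quantize Integer-pixel quantization of marker observations.
#' @param start_offset Video clock offset in 600 Hz frames.
#' @param cam Optional pre-built [camera_model()] overriding `camera_angle`.
#' @return List with `trial2d` (metre units), `mapping`, and `camera`.
#' @export
observe_and_calibrate <- function(trial, camera_angle = 90,
                                  calibration = c("grid2d", "line1d"),
                                  grid_translation = 0, grid_rotation = 0,
                                  height_error = 0, noise_px = 1, seed = 1,
                                  quantize = FALSE, start_offset = 0L,
                                  cam = NULL) {
  calibration <- match.arg(calibration)
  if (is.null(cam)) cam <- camera_model(camera_angle)
  mapping <- if (calibration == "grid2d") {
    g <- grid_spec(translation = grid_translation, rotation = grid_rotation)
    gi <- image_grid(cam, g, noise_px = noise_px, seed = seed + 104729L)
    fit_grid_homography(gi$image, gi$plane, provenance = g)
  } else {
    hl <- height_line_pixels(cam, trial, frame = 0L, noise_px = noise_px,
                             seed = seed + 104729L)
    # the analyst orients the image horizontal axis to match the fall plane
    h_sign <- if (cam$R["right", 1] >= 0) 1 else -1
    fit_height_scale(hl$head_pixel, hl$foot_pixel,
                     assumed_height = trial$meta$participant_height +
                       height_error,
                     h_sign = h_sign,
                     provenance = list(true_height =
                                         trial$meta$participant_height))
  }
  obs <- observe_with_camera(trial, cam, noise_px = noise_px, seed = seed,
                             quantize = quantize, start_offset = start_offset)
  list(trial2d = apply_calibration(mapping, obs), mapping = mapping,
       camera = cam)
}

#' Accuracy sweep over a methodological dimension
#'
#' Reruns the full comparison over a batch of 3D trials while varying one
#' methodological variable — video-side filter cutoff, camera angle,
#' calibration-grid translation or rotation, assumed-height error, or fall
#' direction — and returns tidy per-record results plus a per-value
#' aggregate. Percent measures are averaged within each fall before
#' aggregation across falls.
#'
#' @param trials List of [trial3d()] objects.
#' @param dimension One of `"cutoff"`, `"camera_angle"`,
#'   `"grid_translation"`, `"grid_rotation"`, `"height_error"`,
#'   `"fall_direction"`.
#' @param values Values the dimension takes.
#' @param cutoff Video-side cutoff for non-cutoff sweeps, Hz.
#' @param camera_angle Camera angle for non-camera sweeps.
#' @param calibration Calibration technique for non-calibration sweeps.
#' @param noise_px Digitization noise, pixels.
#' @param seed Base seed.
#' @param gt Optional precomputed [build_ground_truth()] result.
#' @return List with `records` (tidy, with a `value` column) and `summary`
#'   (mean +/- SE per value x outcome, falls as the unit of analysis).
#' @export
run_sweep <- function(trials, dimension = c("cutoff", "camera_angle",
                                            "grid_translation",
                                            "grid_rotation", "height_error",
                                            "fall_direction"),
                      values, cutoff = 10, camera_angle = 90,
                      calibration = "grid2d", noise_px = 1, seed = 1,
                      gt = NULL) {
  dimension <- match.arg(dimension)
  stopifnot(length(trials) > 0, length(values) > 0)
  if (is.null(gt)) gt <- build_ground_truth(trials)
  if (dimension == "fall_direction") {
    recs <- batch_records(trials, gt, cutoff = cutoff,
                          camera_angle = camera_angle,
                          calibration = calibration, noise_px = noise_px,
                          seed = seed)
    recs <- recs[recs$direction %in% values, ]
    recs$value <- recs$direction
  } else {
    per_value <- lapply(values, function(val) {
      args <- list(cutoff = cutoff, camera_angle = camera_angle,
                   calibration = calibration, grid_translation = 0,
                   grid_rotation = 0, height_error = 0,
                   noise_px = noise_px, seed = seed)
      args[[dimension]] <- val
      if (dimension %in% c("grid_translation", "grid_rotation")) {
        args$calibration <- "grid2d"
      }
      if (dimension == "height_error") args$calibration <- "line1d"
      r <- do.call(batch_records, c(list(trials = trials, gt = gt), args))
      r$value <- val
      r
    })
    recs <- do.call(rbind, per_value)
  }
  list(records = recs,
       summary = summarize_by_fall(recs, c("value", "outcome")))
}

# Observe/calibrate/process/compare every trial under one configuration.
batch_records <- function(trials, gt, cutoff, camera_angle, calibration,
                          grid_translation = 0, grid_rotation = 0,
                          height_error = 0, noise_px = 1, seed = 1) {
  cams <- list()
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    oc <- observe_and_calibrate(tr, camera_angle = camera_angle,
                                calibration = calibration,
                                grid_translation = grid_translation,
                                grid_rotation = grid_rotation,
                                height_error = height_error,
                                noise_px = noise_px, seed = seed + i)
    gset <- gt$sets[[tr$meta$trial_id]]
    tset <- process_test_side(oc$trial2d, gset, cutoff = cutoff)
    compare_signal_sets(tset, gset)
  })
  do.call(rbind, rows)
}

# Average within fall (across body parts), then mean +/- SE across falls.
summarize_by_fall <- function(records, group_by) {
  per_fall <- aggregate_accuracy(records,
                                 group_by = c(group_by, "trial_id"))
  names(per_fall) <- sub("_mean$", "", names(per_fall))
  keep <- c(group_by, "trial_id", "rmse", "nrmse", "peak_diff_raw",
            "peak_diff_pct")
  per_fall <- per_fall[intersect(keep, names(per_fall))]
  aggregate_accuracy(per_fall, group_by = group_by)
}

#' Cutoff-comparison accuracy table
#'
#' Builds the central accuracy table of the validation: rows compare the
#' 20 Hz-filtered ground truth (Q20) to video-side signals filtered at each
#' cutoff (Q20-K14 ... Q20-K3) and to the ground-truth source itself
#' refiltered at the same cutoffs (Q20-Q14 ... Q20-Q3, the no-digitization
#' lower bound), under the ideal 90-degree / grid-in-plane configuration.
#' Columns are RMSE and NRMSE for vertical and horizontal position, and
#' RMSE, NRMSE, and raw/percent peak-velocity differences for vertical and
#' horizontal velocity (mean +/- SE across falls; percent measures averaged
#' per fall first).
#'
#' @param trials List of [trial3d()] objects.
#' @param cutoffs Video-side cutoffs, Hz.
#' @param camera_angle,calibration,noise_px,seed Video-side configuration.
#' @param gt Optional precomputed ground truth.
#' @return List with `records` (tidy rows labelled by comparison) and
#'   `table` (one aggregated row per comparison x outcome).
#' @export
table_one <- function(trials, cutoffs = c(3, 5, 7, 10, 12, 14),
                      camera_angle = 90, calibration = "grid2d",
                      noise_px = 1, seed = 1, gt = NULL) {
  if (is.null(gt)) gt <- build_ground_truth(trials)
  all_rows <- list()
  # video side: one observation per trial, reprocessed at each cutoff
  video <- lapply(seq_along(trials), function(i) {
    observe_and_calibrate(trials[[i]], camera_angle = camera_angle,
                          calibration = calibration, noise_px = noise_px,
                          seed = seed + i)$trial2d
  })
  for (cf in sort(cutoffs, decreasing = TRUE)) {
    for (i in seq_along(trials)) {
      id <- trials[[i]]$meta$trial_id
      gset <- gt$sets[[id]]
      kset <- process_test_side(video[[i]], gset, cutoff = cf)
      rk <- compare_signal_sets(kset, gset)
      rk$comparison <- sprintf("Q20-K%g", cf)
      qset <- process_test_side(trials[[i]], gset, cutoff = cf)
      rq <- compare_signal_sets(qset, gset)
      rq$comparison <- sprintf("Q20-Q%g", cf)
      all_rows[[length(all_rows) + 1L]] <- rbind(rk, rq)
    }
  }
  records <- do.call(rbind, all_rows)
  list(records = records,
       table = summarize_by_fall(records, c("comparison", "outcome")))
}

#' Format an accuracy table with the reporting rounding convention
#'
#' Applies the display convention used for accuracy tables: position
#' values below 0.001 m are rounded up to 0.001, and velocity values below
#' 0.01 m/s are rounded up to 0.01.
#'
#' @param tab The `table` element of a [table_one()] result.
#' @return Data frame of formatted character cells.
#' @export
format_table_one <- function(tab) {
  out <- tab
  is_pos <- grepl("^pos_[hv]$", tab$outcome)
  is_vel <- grepl("^vel_[hv]$", tab$outcome)
  fmt <- function(x, lo, digits) {
    ifelse(is.na(x), "", formatC(pmax(x, lo), format = "f", digits = digits))
  }
  out$rmse <- ifelse(is_pos, fmt(tab$rmse_mean, 0.001, 3),
                     ifelse(is_vel, fmt(tab$rmse_mean, 0.01, 2),
                            formatC(tab$rmse_mean, format = "f", digits = 1)))
  out$nrmse <- formatC(tab$nrmse_mean, format = "f", digits = 1)
  out
}

#' Ground-truth summary kinematics of a batch
#'
#' Mean head vertical and horizontal displacement, head rotation, and peak
#' linear/angular velocities across falls, computed from the ground-truth
#' signal sets over each fall interval.
#'
#' @param gt A [build_ground_truth()] result.
#' @return Named numeric vector of means across falls.
#' @export
ground_truth_summary <- function(gt) {
  rows <- lapply(gt$sets, function(s) {
    iv <- s$interval
    a <- iv[1] + 1L
    b <- iv[2]
    head_v <- s$pos$head[a:b, "v"]
    head_h <- s$pos$head[a:b, "h"]
    head_ang <- s$ang$head[a:b]
    data.frame(
      vert_disp = max(head_v) - min(head_v),
      horiz_disp = max(head_h) - min(head_h),
      rotation = max(head_ang) - min(head_ang),
      peak_vv = max(abs(s$vel$head[a:b, "v"])),
      peak_hv = max(abs(s$vel$head[a:b, "h"])),
      peak_av = max(abs(s$angvel$head[a:b])))
  })
  colMeans(do.call(rbind, rows))
}
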