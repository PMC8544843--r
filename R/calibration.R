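#' Pinhole camera model
#'
#' A perspective camera observing the fall plane (the world X–Z plane at
#' Y = 0). The camera sits at `distance` from the scene centre, horizontally
#' offset so its axis makes `angle_to_fall_plane` degrees with the plane
#' (90 = perpendicular, the ideal surveillance geometry), at height
#' `height`, looking at the scene centre. Default intrinsics place a
#' 4 m-wide scene across the 640-pixel image at 3.5 m (focal length
#' 560 px), with the principal point at the image centre. Pixel coordinates
#' have their origin at the top-left with the vertical axis pointing down,
#' as in video imagery.
#'
#' @param angle_to_fall_plane Camera angle in degrees, in (0, 90].
#' @param distance Distance from scene centre in metres.
#' @param height Camera (and scene-centre) height in metres.
#' @param focal_px Focal length in pixels.
#' @param principal_point Pixel coordinates of the principal point.
#' @param resolution Image resolution `c(width, height)` in pixels.
#' @param centre Scene centre `c(x, y)` on the fall plane (z = `height`).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(angle_to_fall_plane = 90, distance = 3.5,
                         height = 0.8, focal_px = 560,
                         principal_point = c(320, 240),
                         resolution = c(640, 480), centre = c(0, 0)) {
  stopifnot(angle_to_fall_plane > 0, angle_to_fall_plane <= 90,
            distance > 0, focal_px > 0)
  th <- angle_to_fall_plane * pi / 180
  target <- c(centre[1], centre[2], height)
  pos <- target + distance * c(-cos(th), sin(th), 0)
  fwd <- (target - pos) / sqrt(sum((target - pos)^2))
  up <- c(0, 0, 1)
  right <- c(fwd[2] * up[3] - fwd[3] * up[2],
             fwd[3] * up[1] - fwd[1] * up[3],
             fwd[1] * up[2] - fwd[2] * up[1])
  right <- right / sqrt(sum(right^2))
  cam_up <- c(right[2] * fwd[3] - right[3] * fwd[2],
              right[3] * fwd[1] - right[1] * fwd[3],
              right[1] * fwd[2] - right[2] * fwd[1])
  structure(
    list(angle = angle_to_fall_plane, distance = distance, height = height,
         focal_px = focal_px, principal_point = principal_point,
         resolution = resolution, position = pos,
         R = rbind(right = right, up = cam_up, forward = fwd)),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model: %g deg to fall plane, %g m range, f = %g px>\n",
              x$angle, x$distance, x$focal_px))
  invisible(x)
}

#' Project 3D world points to pixels
#'
#' Standard perspective projection. Points at or behind the camera plane
#' raise an error. Optional quantization rounds to integer pixels (at most
#' 0.5 px additional error per axis).
#'
#' @param cam A [camera_model()].
#' @param p Numeric vector `c(x, y, z)` or an `n x 3` matrix of points.
#' @param quantize Round to integer pixels?
#' @return Pixel coordinates: length-2 vector or `n x 2` matrix
#'   (columns u, v; v increases downward).
#' @export
project_point <- function(cam, p, quantize = FALSE) {
  one <- is.null(dim(p))
  if (one) p <- matrix(p, 1L)
  d <- sweep(p, 2L, cam$position)
  xc <- d %*% cam$R["right", ]
  yc <- d %*% cam$R["up", ]
  zc <- d %*% cam$R["forward", ]
  if (any(zc <= 1e-6)) stop("point at or behind the camera plane")
  u <- cam$principal_point[1] + cam$focal_px * xc / zc
  v <- cam$principal_point[2] - cam$focal_px * yc / zc
  out <- cbind(u = as.numeric(u), v = as.numeric(v))
  if (quantize) out <- round(out)
  if (one) out[1L, ] else out
}

#' Calibration grid specification
#'
#' A square planar grid of dots used for 2D video calibration: 1.6 x 1.6 m
#' with a 5 x 5 array of dots spaced 0.40 m apart. At baseline it lies in
#' the fall plane, centred on the scene centre; it can be translated along
#' the plane normal (positive toward the camera) and rotated about the
#' vertical axis through its centre.
#'
#' @param size Grid edge length in metres.
#' @param n_dots Dots per side.
#' @param translation Signed offset from the fall plane in metres (positive
#'   toward the camera); supported range +/-0.5 m.
#' @param rotation Rotation about the vertical in degrees; range +/-45.
#' @param centre_height Height of the grid centre in metres.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(size = 1.6, n_dots = 5, translation = 0, rotation = 0,
                      centre_height = 0.8) {
  if (abs(translation) > 0.5 + 1e-9) {
    stop("grid translation outside the supported +/-0.5 m range")
  }
  if (abs(rotation) > 45 + 1e-9) {
    stop("grid rotation outside the supported +/-45 degree range")
  }
  structure(list(size = size, n_dots = as.integer(n_dots),
                 spacing = size / (n_dots - 1L),
                 translation = translation, rotation = rotation,
                 centre_height = centre_height),
            class = "grid_spec")
}

#' Perturb a calibration grid
#'
#' Returns a copy of the grid displaced by `translation` metres along the
#' fall-plane normal (positive toward the camera, negative away) and/or
#' rotated by `rotation` degrees about the vertical axis, emulating
#' imperfect placement of the calibration frame at the scene of a fall.
#'
#' @param g A [grid_spec()].
#' @param translation,rotation Perturbations to apply (absolute, not
#'   cumulative).
#' @return A new `grid_spec`.
#' @export
perturb_grid <- function(g, translation = 0, rotation = 0) {
  stopifnot(inherits(g, "grid_spec"))
  grid_spec(size = g$size, n_dots = g$n_dots, translation = translation,
            rotation = rotation, centre_height = g$centre_height)
}

#' Grid dot coordinates
#'
#' World 3D positions of the grid dots (after translation/rotation), and
#' the nominal fall-plane coordinates the calibration software believes
#' them to occupy (as if the grid lay exactly in the fall plane).
#'
#' @param g A [grid_spec()].
#' @return List with `world` (`n^2 x 3`) and `plane` (`n^2 x 2`, columns
#'   horizontal/vertical fall-plane coordinates).
#' @export
grid_dots <- function(g) {
  half <- g$size / 2
  loc <- seq(-half, half, length.out = g$n_dots)
  gg <- expand.grid(gx = loc, gz = loc)
  rho <- g$rotation * pi / 180
  world <- cbind(gg$gx * cos(rho),
                 g$translation + gg$gx * sin(rho),
                 g$centre_height + gg$gz)
  plane <- cbind(h = gg$gx, v = g$centre_height + gg$gz)
  list(world = world, plane = plane)
}

#' Image of the calibration grid
#'
#' Projects the grid dots through a camera and optionally adds seeded
#' Gaussian pixel noise emulating manual digitization of the dots.
#'
#' @param cam A [camera_model()].
#' @param g A [grid_spec()].
#' @param noise_px Standard deviation of isotropic pixel noise.
#' @param seed Optional seed for the noise.
#' @return List with `image` (`n^2 x 2` pixels) and `plane` (nominal
#'   fall-plane coordinates of the dots).
#' @export
image_grid <- function(cam, g, noise_px = 0, seed = NULL) {
  dots <- grid_dots(g)
  px <- project_point(cam, dots$world)
  if (noise_px > 0) {
    if (!is.null(seed)) {
      old <- local_seed(seed)
      on.exit(restore_seed(old))
    }
    px <- px + matrix(stats::rnorm(length(px), 0, noise_px), ncol = 2L)
  }
  list(image = px, plane = dots$plane)
}

normalize_points <- function(p) {
  ctr <- colMeans(p)
  d <- sqrt(rowSums(sweep(p, 2L, ctr)^2))
  s <- sqrt(2) / mean(d)
  t_mat <- rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
  list(T = t_mat, p = cbind(s * (p[, 1] - ctr[1]), s * (p[, 2] - ctr[2])))
}

#' Fit a plane homography from grid correspondences
#'
#' Least-squares planar homography (normalized direct linear transform)
#' mapping pixel coordinates to fall-plane coordinates, from at least four
#' non-collinear dot correspondences. This models the perspective-grid
#' calibration of 2D digitization software.
#'
#' @param image_dots `n x 2` pixel coordinates of the imaged dots.
#' @param world_dots `n x 2` fall-plane coordinates (horizontal, vertical)
#'   assigned to the dots.
#' @param provenance Optional [grid_spec()] or list recorded with the
#'   mapping.
#' @return A `calibration_mapping` of kind `"grid2d"` with the 3x3
#'   homography `H` (pixel homogeneous to plane) and the reprojection RMS
#'   in plane units.
#' @export
fit_grid_homography <- function(image_dots, world_dots, provenance = NULL) {
  image_dots <- as.matrix(image_dots)
  world_dots <- as.matrix(world_dots)
  n <- nrow(image_dots)
  stopifnot(n == nrow(world_dots))
  if (n < 4L) stop("need at least 4 correspondences")
  for (p in list(image_dots, world_dots)) {
    sv <- svd(sweep(p, 2L, colMeans(p)))$d
    if (sv[2] < 1e-8 * max(sv[1], 1)) {
      stop("degenerate (collinear) dot configuration")
    }
  }
  ni <- normalize_points(image_dots)
  nw <- normalize_points(world_dots)
  a_rows <- lapply(seq_len(n), function(i) {
    x <- ni$p[i, 1]; y <- ni$p[i, 2]
    xp <- nw$p[i, 1]; yp <- nw$p[i, 2]
    rbind(c(-x, -y, -1, 0, 0, 0, x * xp, y * xp, xp),
          c(0, 0, 0, -x, -y, -1, x * yp, y * yp, yp))
  })
  a_mat <- do.call(rbind, a_rows)
  h <- svd(a_mat)$v[, 9L]
  hn <- matrix(h, 3L, 3L, byrow = TRUE)
  h_full <- solve(nw$T) %*% hn %*% ni$T
  h_full <- h_full / h_full[3L, 3L]
  mapped <- apply_homography(h_full, image_dots)
  rms <- sqrt(mean(rowSums((mapped - world_dots)^2)))
  structure(list(kind = "grid2d", H = h_full, reprojection_rms = rms,
                 provenance = provenance),
            class = "calibration_mapping")
}

apply_homography <- function(h_mat, px) {
  w <- cbind(px, 1) %*% t(h_mat)
  cbind(w[, 1] / w[, 3], w[, 2] / w[, 3])
}

#' Fit a 1D height-based calibration
#'
#' Single isotropic metres-per-pixel scale from a vertical line spanning
#' the standing participant, set equal to the (assumed) participant height.
#' The scale inherits any error in the assumed height proportionally, which
#' inflates or deflates all reconstructed lengths but leaves angles
#' unchanged.
#'
#' @param head_pixel,foot_pixel Pixel coordinates of the top of the head
#'   and the base of the foot in a standing frame.
#' @param assumed_height Height assigned to the line, metres.
#' @param h_sign +1 or -1: orientation of the image horizontal axis
#'   relative to the fall-plane horizontal (chosen by the analyst; a
#'   camera on the opposite side of the fall plane mirrors the image).
#' @param provenance Optional record (e.g. true height) kept with the
#'   mapping.
#' @return A `calibration_mapping` of kind `"line1d"` with `scale` (m/px)
#'   and `origin` (the foot pixel).
#' @export
fit_height_scale <- function(head_pixel, foot_pixel, assumed_height,
                             h_sign = 1, provenance = NULL) {
  d <- sqrt(sum((head_pixel - foot_pixel)^2))
  if (d == 0) stop("zero pixel distance between head and foot")
  stopifnot(assumed_height > 0, h_sign %in% c(-1, 1))
  structure(list(kind = "line1d", scale = assumed_height / d,
                 origin = foot_pixel, h_sign = h_sign,
                 provenance = c(list(assumed_height = assumed_height),
                                provenance)),
            class = "calibration_mapping")
}

#' @export
print.calibration_mapping <- function(x, ...) {
  if (x$kind == "grid2d") {
    cat(sprintf("<calibration_mapping grid2d: reprojection RMS %.4g m>\n",
                x$reprojection_rms))
  } else {
    cat(sprintf("<calibration_mapping line1d: %.5g m/px>\n", x$scale))
  }
  invisible(x)
}

#' Apply a calibration mapping to a pixel-unit 2D trial
#'
#' Converts a [trial2d()] from pixels to metres: a `grid2d` mapping applies
#' the plane homography sample-by-sample; a `line1d` mapping applies the
#' isotropic scale about its origin pixel (with the image vertical axis
#' flipped to vertical-up).
#'
#' @param map A `calibration_mapping`.
#' @param trial A `trial2d` with `unit = "pixel"`.
#' @return A `trial2d` with `unit = "metre"` (horizontal, vertical-up).
#' @export
apply_calibration <- function(map, trial) {
  stopifnot(inherits(map, "calibration_mapping"), inherits(trial, "trial2d"))
  if (trial$unit != "pixel") {
    stop("trial is already in metre units; calibration applies to pixels")
  }
  markers <- lapply(trial$markers, function(m) {
    out <- if (map$kind == "grid2d") {
      apply_homography(map$H, m)
    } else {
      cbind(map$h_sign * map$scale * (m[, 1] - map$origin[1]),
            -map$scale * (m[, 2] - map$origin[2]))
    }
    colnames(out) <- c("h", "v")
    out
  })
  trial2d(trial$meta, markers, camera_angle = trial$camera_angle,
          unit = "metre", resolution = trial$resolution, flags = trial$flags)
}

#' Serialize / restore a calibration mapping as JSON
#'
#' @param map A `calibration_mapping`.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return JSON string (or `path` invisibly).
#' @export
calibration_to_json <- function(map, path = NULL) {
  obj <- list(kind = map$kind)
  if (map$kind == "grid2d") {
    obj$H <- map$H
    obj$reprojection_rms <- map$reprojection_rms
  } else {
    obj$scale <- map$scale
    obj$origin <- map$origin
    obj$h_sign <- map$h_sign
  }
  obj$provenance <- map$provenance
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname calibration_to_json
#' @param json JSON string or file path produced by [calibration_to_json()].
#' @export
calibration_from_json <- function(json) {
  obj <- if (file.exists(json)) jsonlite::read_json(json, simplifyVector = TRUE)
         else jsonlite::fromJSON(json)
  if (obj$kind == "grid2d") {
    structure(list(kind = "grid2d", H = matrix(unlist(obj$H), 3L, 3L),
                   reprojection_rms = obj$reprojection_rms,
                   provenance = obj$provenance),
              class = "calibration_mapping")
  } else {
    structure(list(kind = "line1d", scale = obj$scale,
                   origin = unlist(obj$origin),
                   h_sign = if (is.null(obj$h_sign)) 1 else obj$h_sign,
                   provenance = obj$provenance),
              class = "calibration_mapping")
  }
}

#' Height-line pixel endpoints from a standing frame
#'
#' Projects the standing participant's foot base and head top through a
#' camera, providing the endpoints a user would click for 1D height
#' calibration. The foot base sits below the ankle marker on the ground;
#' the head top sits above the head marker by the anthropometric
#' head-marker-to-vertex offset.
#'
#' @param cam A [camera_model()].
#' @param trial A [trial3d()] containing `ankle` and `head` markers.
#' @param frame 0-based standing frame index (default 0).
#' @param noise_px Pixel noise added to each endpoint.
#' @param seed Optional seed for the noise.
#' @return List with `head_pixel` and `foot_pixel`.
#' @export
height_line_pixels <- function(cam, trial, frame = 0L, noise_px = 0,
                               seed = NULL) {
  stopifnot(inherits(trial, "trial3d"))
  i <- as.integer(frame) + 1L
  h <- trial$meta$participant_height
  fr <- anthropometry(h)
  ankle <- trial$markers$ankle[i, ]
  head <- trial$markers$head[i, ]
  foot_w <- c(ankle[1], ankle[2], ankle[3] - fr["ankle_height"])
  head_w <- c(head[1], head[2], head[3] + fr["vertex_offset"])
  px <- project_point(cam, rbind(foot_w, head_w))
  if (noise_px > 0) {
    if (!is.null(seed)) {
      old <- local_seed(seed)
      on.exit(restore_seed(old))
    }
    px <- px + matrix(stats::rnorm(4, 0, noise_px), ncol = 2L)
  }
  list(head_pixel = px[2L, ], foot_pixel = px[1L, ])
}
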