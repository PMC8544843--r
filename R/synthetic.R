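# Seed hygiene: generators restore the caller's RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Translating-platform perturbation profile
#'
#' Trapezoidal-velocity platform translation used to induce slip/trip-like
#' falls: acceleration at 10 m/s^2 up to 2.2 m/s, a constant-velocity
#' plateau, then mirror-image deceleration, over a total of 0.6 s.
#'
#' @param t Time(s) in seconds from perturbation onset (vectorized).
#' @param acceleration Ramp acceleration, m/s^2.
#' @param plateau_velocity Plateau velocity, m/s.
#' @param total_duration Total perturbation duration, s.
#' @return Data frame with columns `t`, `displacement`, `velocity`,
#'   `acceleration`.
#' @export
platform_profile <- function(t, acceleration = 10, plateau_velocity = 2.2,
                             total_duration = 0.6) {
  stopifnot(all(t >= 0), acceleration > 0, plateau_velocity > 0)
  t1 <- plateau_velocity / acceleration
  if (2 * t1 > total_duration + 1e-12) {
    stop("ramp phases exceed total duration")
  }
  t2 <- total_duration - t1
  d1 <- 0.5 * acceleration * t1^2
  d2 <- d1 + plateau_velocity * (t2 - t1)
  disp <- vel <- acc <- numeric(length(t))
  ramp_up <- t < t1
  plateau <- t >= t1 & t < t2
  ramp_dn <- t >= t2 & t < total_duration
  done <- t >= total_duration
  acc[ramp_up] <- acceleration
  vel[ramp_up] <- acceleration * t[ramp_up]
  disp[ramp_up] <- 0.5 * acceleration * t[ramp_up]^2
  vel[plateau] <- plateau_velocity
  disp[plateau] <- d1 + plateau_velocity * (t[plateau] - t1)
  acc[ramp_dn] <- -acceleration
  td <- t[ramp_dn] - t2
  vel[ramp_dn] <- plateau_velocity - acceleration * td
  disp[ramp_dn] <- d2 + plateau_velocity * td - 0.5 * acceleration * td^2
  disp[done] <- d2 + plateau_velocity * (total_duration - t2) -
    0.5 * acceleration * (total_duration - t2)^2
  data.frame(t = t, displacement = disp, velocity = vel, acceleration = acc)
}

#' Anthropometric segment fractions
#'
#' Segment lengths as fractions of standing height, from standard
#' anthropometric tables (shank = ankle-to-knee, thigh = knee-to-hip, trunk
#' = hip-to-shoulder, neck = shoulder-to-head-marker; plus marker offsets
#' for the foot base and head vertex used by 1D height calibration).
#'
#' @param height Participant height in metres.
#' @return Named numeric vector of segment lengths in metres.
#' @export
anthropometry <- function(height) {
  c(shank = 0.246 * height,
    thigh = 0.245 * height,
    trunk = 0.288 * height,
    neck = 0.130 * height,
    upper_arm = 0.186 * height,
    forearm = 0.146 * height,
    ankle_height = 0.039 * height,
    vertex_offset = 0.052 * height)
}

minimum_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# absolute chain angles (deg, ankle-up build direction) per fall direction
.posture <- list(
  forward = list(stand = c(shank = 90, thigh = 90, trunk = 90, neck = 90,
                           upper_arm = -90, forearm = -90),
                 land = c(shank = 40, thigh = 8, trunk = 4, neck = 4,
                          upper_arm = -30, forearm = -10),
                 rot_sign = 1),
  backward = list(stand = c(shank = 90, thigh = 90, trunk = 90, neck = 90,
                            upper_arm = -90, forearm = -90),
                  land = c(shank = 115, thigh = 165, trunk = 174, neck = 174,
                           upper_arm = -150, forearm = -168),
                  rot_sign = -1),
  sideways = list(stand = c(shank = 90, thigh = 90, trunk = 90, neck = 90,
                            upper_arm = -90, forearm = -90),
                  land = c(shank = 40, thigh = 12, trunk = 7, neck = 7,
                           upper_arm = -25, forearm = -8),
                  rot_sign = 1)
)

# transition-onset delays as fractions of the descent duration
.joint_delay <- c(shank = 0.06, thigh = 0.02, trunk = 0, neck = 0.05,
                  upper_arm = 0.18, forearm = 0.22)

default_out_of_plane <- function(direction) {
  switch(direction,
    backward = c(head = 0.08, shoulder = 0.08, elbow = 0.11, wrist = 0.161,
                 GT = 0.06, knee = 0.08, ankle = 0.03),
    forward = c(head = 0.09, shoulder = 0.09, elbow = 0.12, wrist = 0.13,
                GT = 0.08, knee = 0.10, ankle = 0.06),
    sideways = c(head = 0.15, sternum = 0.13, shoulder = 0.14,
                 elbow = 0.195, wrist = 0.17, ASIS = 0.172, knee = 0.207,
                 ankle = 0.08)
  )
}

#' Simulate a 3D fall trial
#'
#' Kinematic-template generator: a planar linked-segment body
#' (ankle-knee-hip-shoulder-head plus shoulder-elbow-wrist, segment lengths
#' from [anthropometry()]) whose chain angles rotate from standing to a
#' direction-appropriate landed posture with a raised-cosine angular
#' velocity profile: velocity builds smoothly to its terminal (impact)
#' value over the descent, then is absorbed by a short raised-cosine
#' arrest representing mat compression. This places realistic energy in
#' the 3-10 Hz band around impact while keeping content above 10 Hz
#' negligible, consistent with the observed 1-10 Hz frequency content of
#' fall movements. Perturbation-initiated falls translate the feet with
#' the [platform_profile()]; self-initiated falls add a slow 0.5 Hz
#' pre-fall sway instead. Out-of-plane (Y) excursions are smooth
#' raised-cosine bumps with per-marker peak amplitudes; defaults are
#' direction-specific and jittered by `±jitter`, while amplitudes passed
#' explicitly are honoured exactly. The generator is deterministic under a
#' fixed seed and event frames (fall initiation, cessation of movement)
#' are annotated. It is a prescribed-trajectory template, not a dynamic
#' (force-based) simulation.
#'
#' @param direction Fall direction.
#' @param initiation `"perturbation"` or `"self_initiated"`.
#' @param participant_height Standing height, metres.
#' @param duration Nominal descent duration, seconds.
#' @param out_of_plane Optional named vector of per-marker peak Y
#'   amplitudes (m); `NULL` uses jittered direction-specific defaults.
#'   Use `0` amplitudes for a perfectly planar fall.
#' @param arrest_time Duration of the landing arrest (mat compression), s.
#'   Shorter arrests put more energy near the top of the 3-10 Hz band.
#' @param bounce Restitution fraction: rebound velocity at the end of the
#'   arrest as a fraction of impact velocity (0 disables the rebound).
#' @param bounce_hz,bounce_decay Frequency (Hz) and exponential decay time
#'   constant (s) of the post-impact rebound oscillation.
#' @param jitter Relative seeded variability applied to timings and default
#'   amplitudes.
#' @param rate Sampling rate, Hz (motion-capture side, 600 nominal).
#' @param seed Integer seed (the caller's RNG state is preserved).
#' @param trial_id Identifier; autogenerated when `NULL`.
#' @return A [trial3d()].
#' @export
simulate_fall <- function(direction = c("forward", "backward", "sideways"),
                          initiation = c("perturbation", "self_initiated"),
                          participant_height = 1.70, duration = 1.05,
                          out_of_plane = NULL, arrest_time = 0.10,
                          bounce = 0.65, bounce_hz = 3.5,
                          bounce_decay = 0.35, jitter = 0.10, rate = 600,
                          seed = 1, trial_id = NULL) {
  direction <- match.arg(direction)
  initiation <- match.arg(initiation)
  stopifnot(participant_height > 1.0, participant_height < 2.5, rate > 0)
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  post <- .posture[[direction]]
  frac <- anthropometry(participant_height)
  pre <- 0.4                                 # standing lead-in, s
  td <- duration * (1 + stats::runif(1, -jitter, jitter))
  if (initiation == "perturbation" && td <= 0.6) td <- 0.62
  total <- pre + td + arrest_time + 0.85
  n <- floor(total * rate) + 1L
  t <- (seq_len(n) - 1L) / rate
  tf <- t - pre                              # time from fall initiation

  ang_names <- names(post$stand)
  delays <- .joint_delay * td
  land <- post$land + stats::runif(length(ang_names), -5, 5)
  names(land) <- ang_names
  ta <- arrest_time * (1 + stats::runif(1, -jitter, jitter))
  f_b <- bounce_hz * (1 + stats::runif(1, -jitter, jitter))
  tau_b <- bounce_decay * (1 + stats::runif(1, -jitter, jitter))

  # Each chain angle follows a raised-cosine velocity profile: angular
  # velocity builds from zero to its terminal (impact) value over the
  # descent, is absorbed by a raised-cosine arrest of duration `ta` (mat
  # compression) ending with a rebound velocity of `bounce` times the
  # impact velocity, and rings out as a damped low-frequency bounce. The
  # junctions are velocity-continuous, so spectral content stays
  # essentially below ~1.5/ta Hz.
  ang <- matrix(NA_real_, n, length(ang_names),
                dimnames = list(NULL, ang_names))
  wb <- 2 * pi * f_b
  for (j in ang_names) {
    tj <- td - delays[[j]]
    vj <- 2 * (land[[j]] - post$stand[[j]]) / (tj + ta * (1 - bounce))
    ta_d <- pmin(pmax(tf - delays[[j]], 0), tj)
    th_a <- (ta_d - (tj / pi) * sin(pi * ta_d / tj)) / 2
    # arrest: velocity from vj down through zero to -bounce*vj
    ta_b <- pmin(pmax(tf - td, 0), ta)
    th_b <- (1 + bounce) * (ta_b + (ta / pi) * sin(pi * ta_b / ta)) / 2 -
      bounce * ta_b
    # damped rebound oscillation, velocity-matched at the junction
    t_c <- pmax(tf - td - ta, 0)
    th_c <- -(bounce * (1 + stats::runif(1, -jitter, jitter)) / wb) *
      exp(-t_c / tau_b) * sin(wb * t_c)
    th_c[t_c == 0] <- 0
    ang[, j] <- post$stand[[j]] + vj * (th_a + th_b + th_c)
  }
  if (initiation == "self_initiated") {
    # slow anteroposterior sway before and into the fall
    ramp <- pmin(pmax(t / pre, 0), 1)
    ang[, "trunk"] <- ang[, "trunk"] + 1.5 * ramp * sin(2 * pi * 0.5 * t)
  }

  # base (foot) in-plane trajectory: platform translation plus a small
  # foot adjustment (slide and heel lift) so the ankle is never motionless
  x0 <- -post$rot_sign * 0.25
  base_x <- rep(x0, n)
  if (initiation == "perturbation") {
    pp <- platform_profile(pmax(tf, 0))
    base_x <- base_x - post$rot_sign * pp$displacement
  }
  base_x <- base_x + post$rot_sign * 0.03 * minimum_jerk(tf / td)
  # post-impact horizontal skid: damped oscillation with smooth onset
  if (bounce > 0) {
    t_sk <- pmax(tf - td - ta, 0)
    v_sl <- bounce * 1.2 * (1 + stats::runif(1, -jitter, jitter))
    base_x <- base_x + post$rot_sign * minimum_jerk(t_sk / 0.08) *
      (v_sl / wb) * exp(-t_sk / tau_b) * sin(wb * t_sk)
  }
  lift_tau <- pmin(pmax((tf - 0.3 * td) / (0.75 * td), 0), 1)
  ankle_z <- frac[["ankle_height"]] + 0.08 * (1 - cos(2 * pi * lift_tau)) / 2

  rad <- pi / 180
  knee_x <- base_x + frac[["shank"]] * cos(ang[, "shank"] * rad)
  knee_z <- ankle_z + frac[["shank"]] * sin(ang[, "shank"] * rad)
  hip_x <- knee_x + frac[["thigh"]] * cos(ang[, "thigh"] * rad)
  hip_z <- knee_z + frac[["thigh"]] * sin(ang[, "thigh"] * rad)
  sho_x <- hip_x + frac[["trunk"]] * cos(ang[, "trunk"] * rad)
  sho_z <- hip_z + frac[["trunk"]] * sin(ang[, "trunk"] * rad)
  head_x <- sho_x + frac[["neck"]] * cos(ang[, "neck"] * rad)
  head_z <- sho_z + frac[["neck"]] * sin(ang[, "neck"] * rad)
  elb_x <- sho_x + frac[["upper_arm"]] * cos(ang[, "upper_arm"] * rad)
  elb_z <- sho_z + frac[["upper_arm"]] * sin(ang[, "upper_arm"] * rad)
  wri_x <- elb_x + frac[["forearm"]] * cos(ang[, "forearm"] * rad)
  wri_z <- elb_z + frac[["forearm"]] * sin(ang[, "forearm"] * rad)
  ster_x <- sho_x - 0.15 * frac[["trunk"]] * cos(ang[, "trunk"] * rad)
  ster_z <- sho_z - 0.15 * frac[["trunk"]] * sin(ang[, "trunk"] * rad)

  pelvis <- if (direction == "sideways") "ASIS" else "GT"
  xz <- list(head = cbind(head_x, head_z), shoulder = cbind(sho_x, sho_z),
             elbow = cbind(elb_x, elb_z), wrist = cbind(wri_x, wri_z),
             knee = cbind(knee_x, knee_z),
             ankle = cbind(base_x, ankle_z))
  xz[[pelvis]] <- cbind(hip_x, hip_z)
  if (direction == "sideways") xz$sternum <- cbind(ster_x, ster_z)

  amp <- default_out_of_plane(direction)
  exact <- !is.null(out_of_plane)
  if (exact) {
    if (length(out_of_plane) == 1L && is.null(names(out_of_plane))) {
      amp[] <- out_of_plane
    } else {
      amp[names(out_of_plane)] <- out_of_plane
    }
  } else {
    amp <- amp * (1 + stats::runif(length(amp), -jitter, jitter))
  }
  ty <- if (exact) td + 0.2 else (td + 0.2) * (1 + stats::runif(1, -jitter, jitter))
  ybump <- ifelse(tf > 0 & tf < ty, (1 - cos(2 * pi * pmax(tf, 0) / ty)) / 2, 0)

  markers <- lapply(names(xz), function(mk) {
    a <- if (mk %in% names(amp)) amp[[mk]] else 0
    cbind(X = xz[[mk]][, 1L], Y = a * ybump, Z = xz[[mk]][, 2L])
  })
  names(markers) <- names(xz)

  fall_start <- as.integer(round(pre * rate))
  fall_end <- as.integer(round((pre + td + ta + 0.5) * rate))
  if (is.null(trial_id)) {
    trial_id <- sprintf("%s_%s_s%d", direction,
                        if (initiation == "perturbation") "pert" else "self",
                        seed)
  }
  meta <- trial_meta(trial_id, direction, initiation, participant_height,
                     fall_start, fall_end, rate)
  trial3d(meta, markers)
}

#' Simulate a batch of falls
#'
#' Generates the study design: `n_per_cell` perturbation-based and
#' `n_per_cell` self-initiated falls in each of the forward, backward and
#' sideways directions (default 6 + 6 per direction, 36 falls), with
#' per-trial seeds derived from `seed`.
#'
#' @param n_per_cell Falls per direction-by-initiation cell.
#' @param seed Base seed.
#' @param ... Further arguments passed to [simulate_fall()].
#' @return Named list of [trial3d()] objects.
#' @export
simulate_batch <- function(n_per_cell = 6, seed = 1, ...) {
  trials <- list()
  k <- 0L
  for (dir in c("forward", "backward", "sideways")) {
    for (ini in c("perturbation", "self_initiated")) {
      for (i in seq_len(n_per_cell)) {
        k <- k + 1L
        id <- sprintf("%s_%s_%02d", dir,
                      if (ini == "perturbation") "pert" else "self", i)
        trials[[id]] <- simulate_fall(direction = dir, initiation = ini,
                                      seed = seed * 1000L + k,
                                      trial_id = id, ...)
      }
    }
  }
  trials
}

#' Observe a 3D trial with a simulated video camera
#'
#' Projects the 600 Hz 3D markers through a pinhole camera, decimates to
#' the video frame rate by keeping every `rate/video_rate`-th frame, and
#' adds seeded Gaussian pixel noise (optionally integer quantization)
#' standing in for human digitization error. Markers that leave the frame
#' are flagged (continuous coordinates are retained) with a warning.
#'
#' @param trial A [trial3d()].
#' @param cam A [camera_model()].
#' @param noise_px Pixel noise standard deviation (default 1).
#' @param seed Seed for the noise.
#' @param quantize Round observed positions to integer pixels?
#' @param video_rate Video frame rate, Hz (must divide the trial rate).
#' @param start_offset Integer start offset in 600 Hz frames, emulating an
#'   unsynchronized video clock (the pipeline recovers it by
#'   cross-correlation).
#' @return A [trial2d()] in pixel units with the camera angle recorded.
#' @export
observe_with_camera <- function(trial, cam, noise_px = 1, seed = 1,
                                quantize = FALSE, video_rate = 30,
                                start_offset = 0L) {
  stopifnot(inherits(trial, "trial3d"), inherits(cam, "camera_model"))
  step <- trial$meta$sample_rate / video_rate
  if (abs(step - round(step)) > 1e-9) {
    stop("video rate must divide the trial sample rate")
  }
  step <- as.integer(round(step))
  start_offset <- as.integer(start_offset)
  idx <- seq(1L + start_offset, trial$n_frames, by = step)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  res <- cam$resolution
  out <- list()
  flags <- list()
  any_out <- FALSE
  for (mk in names(trial$markers)) {
    px <- project_point(cam, trial$markers[[mk]][idx, , drop = FALSE])
    if (noise_px > 0) {
      px <- px + matrix(stats::rnorm(length(px), 0, noise_px), ncol = 2L)
    }
    if (quantize) px <- round(px)
    off <- px[, 1] < 0 | px[, 1] > res[1] | px[, 2] < 0 | px[, 2] > res[2]
    any_out <- any_out || any(off)
    flags[[mk]] <- off
    out[[mk]] <- px
  }
  if (any_out) warning("marker(s) outside the image frame; values retained")
  m3 <- trial$meta
  fs2 <- as.integer(floor((m3$fall_start_frame - start_offset) / step))
  fe2 <- as.integer(ceiling((m3$fall_end_frame - start_offset) / step))
  meta <- trial_meta(m3$trial_id, m3$direction, m3$initiation,
                     m3$participant_height, max(fs2, 0L),
                     min(fe2, length(idx)), video_rate)
  trial2d(meta, out, camera_angle = cam$angle, unit = "pixel",
          resolution = res, flags = flags)
}

#' Recover platform-perturbation constants from a trial
#'
#' Estimates the perturbation profile from the ankle in-plane trajectory by
#' central-difference differentiation: peak acceleration magnitude, peak
#' velocity magnitude, and active duration (time the platform speed exceeds
#' 5% of its peak).
#'
#' @param trial A perturbation-initiated [trial3d()].
#' @param window_s Search window after fall initiation, s: the platform
#'   acts at fall onset, before landing (post-impact foot skid is thereby
#'   excluded).
#' @return List with `acceleration` (m/s^2), `plateau_velocity` (m/s),
#'   `duration` (s).
#' @export
estimate_platform_profile <- function(trial, window_s = 0.8) {
  stopifnot(inherits(trial, "trial3d"))
  if (trial$meta$initiation != "perturbation") {
    stop("platform profile is defined only for perturbation-initiated falls")
  }
  rate <- trial$meta$sample_rate
  a0 <- trial$meta$fall_start_frame + 1L
  b0 <- min(trial$n_frames, a0 + as.integer(round(window_s * rate)))
  x <- fs_series(trial$markers$ankle[a0:b0, "X"], rate)
  v <- central_difference(x)
  a <- central_difference(v)
  amax <- max(abs(a$values))
  # the platform is active while it accelerates or decelerates; the small
  # voluntary foot adjustments never approach half the ramp acceleration
  active <- which(abs(a$values) > 0.5 * amax)
  list(acceleration = amax,
       plateau_velocity = max(abs(v$values)),
       duration = (max(active) - min(active) + 1L) / rate)
}
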