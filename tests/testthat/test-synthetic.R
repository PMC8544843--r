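test_that("platform profile reproduces the trapezoidal phase values", {
  p <- platform_profile(c(0, 0.22, 0.3, 0.6, 1))
  expect_equal(p$acceleration[1], 10)
  expect_equal(p$velocity[2], 2.2)      # end of the 2.2/10 = 0.22 s ramp
  expect_equal(p$velocity[3], 2.2)      # plateau
  expect_equal(p$velocity[4], 0)        # motion complete at 0.6 s
  expect_equal(p$velocity[5], 0)
  # displacement is monotone and consistent with the phase integrals
  expect_equal(p$displacement[1], 0)
  d_end <- 0.5 * 10 * 0.22^2 + 2.2 * (0.38 - 0.22) + 0.5 * 2.2 * 0.22
  expect_equal(p$displacement[5], d_end, tolerance = 1e-9)
  expect_error(platform_profile(0.1, acceleration = 5, plateau_velocity = 2.2,
                                total_duration = 0.6), "exceed")
})

test_that("the generator is deterministic and seed-sensitive", {
  a <- simulate_fall("sideways", "self_initiated", seed = 7)
  b <- simulate_fall("sideways", "self_initiated", seed = 7)
  expect_identical(a, b)
  c <- simulate_fall("sideways", "self_initiated", seed = 8)
  expect_false(identical(a$markers$head, c$markers$head))
  # the caller's RNG stream is not consumed
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_fall(seed = 3)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("generated falls satisfy the band-limited spectral premise", {
  for (tr in fx_batch()[c(1, 3, 5)]) {
    for (mk in names(tr$markers)) {
      for (ax in c("X", "Z")) {
        s <- fs_series(tr$markers[[mk]][, ax], tr$meta$sample_rate)
        if (diff(range(s$values)) < 1e-9) next
        expect_lt(energy_fraction_above(s, 10), 0.05)
      }
    }
  }
})

test_that("generated falls have plausible whole-body kinematics", {
  gt <- fx_gt()
  gs <- ground_truth_summary(gt)
  expect_gt(gs["peak_vv"], 2.0)   # head peak vertical velocity band, m/s
  expect_lt(gs["peak_vv"], 4.0)
  expect_gt(gs["vert_disp"], 0.8)
  expect_lt(gs["vert_disp"], 1.4)
  # in-plane segment lengths are preserved throughout the fall
  tr <- fx_trial()
  d <- tr$markers$knee[, c("X", "Z")] - tr$markers$ankle[, c("X", "Z")]
  expect_lt(diff(range(sqrt(rowSums(d^2)))), 1e-9)
})

test_that("injected out-of-plane amplitudes are recovered exactly", {
  tr <- simulate_fall("sideways", "perturbation",
                      out_of_plane = c(knee = 0.207, elbow = 0.1), seed = 5,
                      trial_id = "oop")
  s <- out_of_plane_summary(tr)
  expect_equal(s$peak_displacement_m[s$marker == "knee"], 0.207,
               tolerance = 0.005)
  expect_equal(s$peak_displacement_m[s$marker == "elbow"], 0.1,
               tolerance = 0.005)
})

test_that("platform constants are recovered from the ankle trajectory", {
  pp <- estimate_platform_profile(fx_trial())
  expect_equal(pp$acceleration, 10, tolerance = 0.05)
  expect_equal(pp$plateau_velocity, 2.2, tolerance = 0.05)
  expect_equal(pp$duration, 0.6, tolerance = 0.05)
  self <- simulate_fall("forward", "self_initiated", seed = 2)
  expect_error(estimate_platform_profile(self), "perturbation")
})

test_that("camera observation decimates, is seeded, and flags exits", {
  tr <- fx_trial()
  cam <- camera_model(90)
  obs <- observe_with_camera(tr, cam, noise_px = 1, seed = 11)
  expect_s3_class(obs, "trial2d")
  expect_equal(obs$meta$sample_rate, 30)
  expect_equal(obs$n_frames, length(seq(1, tr$n_frames, by = 20)))
  expect_equal(obs$camera_angle, 90)
  expect_identical(obs, observe_with_camera(tr, cam, noise_px = 1, seed = 11))
  # zero-noise observation sits on the projected truth
  clean <- observe_with_camera(tr, cam, noise_px = 0, seed = 1)
  truth <- project_point(cam, tr$markers$head[seq(1, tr$n_frames, 20), ])
  expect_equal(unname(clean$markers$head), unname(truth), tolerance = 1e-9)
  # a camera too close pushes markers out of frame -> warning + flags
  near <- camera_model(90, distance = 1.2)
  expect_warning(off <- observe_with_camera(tr, near, noise_px = 0, seed = 1),
                 "outside")
  expect_true(any(unlist(off$flags)))
})

test_that("pixel noise strictly degrades full-pipeline accuracy", {
  tr <- simulate_fall("forward", "perturbation", out_of_plane = 0, seed = 21,
                      trial_id = "nz")
  gt <- build_ground_truth(list(tr))
  g <- gt$sets[[1]]
  r0 <- compare_signal_sets(process_test_side(
    observe_and_calibrate(tr, 90, noise_px = 0, seed = 3)$trial2d, g, 10), g)
  r1 <- compare_signal_sets(process_test_side(
    observe_and_calibrate(tr, 90, noise_px = 1, seed = 3)$trial2d, g, 10), g)
  for (oc in c("pos_v", "pos_h", "vel_v", "vel_h")) {
    expect_gt(mean(r1$rmse[r1$outcome == oc]),
              mean(r0$rmse[r0$outcome == oc]))
  }
})
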