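test_that("zeroing subtracts the fall-initiation value and is idempotent", {
  m <- list(a = cbind(h = c(1.2, 1.3, 1.5), v = c(0.8, 0.7, 0.5)))
  z <- zero_initial(m, 0)
  expect_equal(z$a[1, ], c(h = 0, v = 0))
  expect_equal(diff(z$a[, "h"]), diff(m$a[, "h"]))
  expect_equal(zero_initial(z, 0), z)
})

test_that("segment angles reproduce axis-aligned cases and unwrap", {
  n <- 5
  prox <- cbind(rep(0, n), rep(0, n))
  expect_equal(segment_angle_series(prox, cbind(rep(1, n), rep(0, n)),
                                    30)$values, rep(0, n))
  expect_equal(segment_angle_series(prox, cbind(rep(0, n), rep(1, n)),
                                    30)$values, rep(90, n))
  # continuity through a rotation past 180 degrees
  th <- seq(0, 2 * pi, length.out = 200)
  a <- segment_angle_series(cbind(0 * th, 0 * th), cbind(cos(th), sin(th)),
                            100)
  expect_lt(max(abs(diff(a$values))), 180)
  expect_equal(a$values[200], 360, tolerance = 1e-6)
})

test_that("segment angles are rotation-equivariant and translation-invariant", {
  set.seed(5)
  prox <- cbind(rnorm(20), rnorm(20))
  dist <- prox + cbind(rnorm(20, 1), rnorm(20, 0.5))
  base <- segment_angle_series(prox, dist, 30)$values
  phi <- 30 * pi / 180
  rot <- function(p) cbind(cos(phi) * p[, 1] - sin(phi) * p[, 2],
                           sin(phi) * p[, 1] + cos(phi) * p[, 2])
  rotated <- segment_angle_series(rot(prox), rot(dist), 30)$values
  expect_equal((rotated - base) %% 360, rep(30, 20), tolerance = 1e-8)
  shifted <- segment_angle_series(prox + 5, dist + 5, 30)$values
  expect_equal(shifted, base)
  expect_error(segment_angle_series(prox, prox, 30), "frame 0")
})

test_that("peak velocity keeps sign, honours intervals, ignores outside data", {
  t <- seq(0, 1, by = 1 / 100)
  v <- fs_series(sin(2 * pi * t), 100)
  pk <- peak_velocity(v)
  expect_equal(abs(pk$peak_value), 1, tolerance = 1e-3)
  expect_equal(pk$peak_time, 0.25, tolerance = 0.01)
  neg <- peak_velocity(fs_series(c(-3, -1, -2), 10))
  expect_equal(neg$peak_value, -3)
  # samples outside the interval cannot influence the peak
  v2 <- fs_series(c(rep(0.1, 50), 9, rep(0.1, 50)), 100)
  expect_equal(peak_velocity(v2, interval = c(0, 40))$peak_value, 0.1)
  expect_error(peak_velocity(v, interval = c(50, 50)), "empty")
  expect_equal(peak_velocity(fs_series(c(-5, 2), 10), criterion = "signed")$peak_value, 2)
})

test_that("out-of-plane summary recovers planar and analytic cases", {
  meta <- trial_meta("p", "forward", "perturbation", 1.7, 0, 600, 600)
  t <- (0:600) / 600
  planar <- trial3d(meta, list(head = cbind(X = t, Y = rep(0.3, 601),
                                            Z = 1 - t)))
  s <- out_of_plane_summary(planar)
  expect_equal(s$peak_displacement_m, 0)
  expect_equal(s$peak_velocity_ms, 0)
  wavy <- trial3d(meta, list(head = cbind(X = t, Y = 0.1 * sin(2 * pi * t),
                                          Z = 1 - t)))
  s2 <- out_of_plane_summary(wavy)
  expect_equal(s2$peak_displacement_m, 0.1, tolerance = 1e-4)
  expect_equal(s2$peak_velocity_ms, 0.2 * pi, tolerance = 1e-3)
})

test_that("resultant horizontal displacement dominates the in-plane component", {
  meta <- trial_meta("r", "forward", "perturbation", 1.7, 0, 3, 600)
  tr <- trial3d(meta, list(head = cbind(X = c(0, 3, 1), Y = c(0, 4, 0),
                                        Z = c(1, 1, 1))))
  r <- resultant_xy(tr)$head
  expect_equal(unname(r[2, "resultant_xy"]), 5)  # 3-4-5 displacement
  expect_equal(unname(r[2, "x_inplane"]), 3)
  tr2 <- fx_trial()
  r2 <- resultant_xy(tr2)
  for (mk in names(r2)) {
    expect_true(all(r2[[mk]][, "resultant_xy"] >=
                      abs(r2[[mk]][, "x_inplane"]) - 1e-12))
  }
})

test_that("in-plane-vs-resultant error grows with injected out-of-plane motion", {
  errs <- vapply(c(0.05, 0.1, 0.2), function(a) {
    tr <- simulate_fall("sideways", "perturbation",
                        out_of_plane = c(knee = a), seed = 9, trial_id = "m")
    r <- resultant_xy(tr)$knee
    iv <- fall_interval(tr)
    idx <- (iv[1] + 1):iv[2]
    sqrt(mean((r[idx, "resultant_xy"] - abs(r[idx, "x_inplane"]))^2))
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
})
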