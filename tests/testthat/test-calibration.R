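test_that("perspective projection matches pinhole closed forms", {
  cam <- camera_model(90)
  # scene centre lies on the optical axis -> principal point
  expect_equal(unname(project_point(cam, c(0, 0, 0.8))),
               unname(cam$principal_point), tolerance = 1e-9)
  # two fall-plane points 0.4 m apart at range D: separation f * 0.4 / D
  p1 <- project_point(cam, c(0, 0, 0.8))
  p2 <- project_point(cam, c(0.4, 0, 0.8))
  expect_equal(abs(p2["u"] - p1["u"]), cam$focal_px * 0.4 / cam$distance,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(project_point(cam, c(0, 10, 0.8)), "behind")
  # quantization stays within half a pixel
  q <- project_point(cam, c(0.123, 0.05, 1.1), quantize = TRUE)
  c0 <- project_point(cam, c(0.123, 0.05, 1.1))
  expect_true(all(abs(q - c0) <= 0.5))
})

test_that("pure depth motion at 90 degrees produces no on-axis image motion", {
  cam <- camera_model(90)
  a <- project_point(cam, c(0, 0, 0.8))
  b <- project_point(cam, c(0, 0.2, 0.8))
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("noise-free grid homography round-trips within a millimetre", {
  for (angle in c(30, 60, 90)) {
    cam <- camera_model(angle)
    gi <- image_grid(cam, grid_spec(), noise_px = 0)
    map <- fit_grid_homography(gi$image, gi$plane)
    expect_lt(map$reprojection_rms, 1e-3)
  }
})

test_that("fronto-parallel calibration reduces to a similarity", {
  cam <- camera_model(90)
  gi <- image_grid(cam, grid_spec(), noise_px = 0)
  map <- fit_grid_homography(gi$image, gi$plane)
  h_norm <- map$H / map$H[3, 3]
  # projective terms vanish and the linear part is a scaled reflection
  expect_equal(unname(h_norm[3, 1:2]), c(0, 0), tolerance = 1e-8)
  expect_equal(abs(h_norm[1, 1]), abs(h_norm[2, 2]), tolerance = 1e-6)
  expect_equal(h_norm[1, 2], 0, tolerance = 1e-8)
})

test_that("digitization noise on grid dots keeps world RMS error small", {
  cam <- camera_model(90)
  errs <- vapply(1:20, function(i) {
    gi <- image_grid(cam, grid_spec(), noise_px = 1, seed = i)
    map <- fit_grid_homography(gi$image, gi$plane)
    clean <- image_grid(cam, grid_spec(), noise_px = 0)
    mapped <- cbind(clean$image, 1) %*% t(map$H)
    mapped <- mapped[, 1:2] / mapped[, 3]
    sqrt(mean(rowSums((mapped - clean$plane)^2)))
  }, numeric(1))
  expect_lt(mean(errs), 0.005)  # < 5 mm at 3.5 m range
})

test_that("degenerate dot configurations are rejected", {
  line <- cbind(1:10, 2 * (1:10))
  expect_error(fit_grid_homography(line, line), "collinear")
  expect_error(fit_grid_homography(cbind(1:3, 1), cbind(1:3, 1)),
               "at least 4")
})

test_that("height-scale calibration follows its closed forms", {
  map <- fit_height_scale(c(320, 60), c(320, 400), assumed_height = 1.70)
  expect_equal(map$scale, 1.70 / 340)
  expect_error(fit_height_scale(c(1, 1), c(1, 1), 1.7), "zero pixel")
  # height error inflates all lengths by (h + dh) / h and leaves angles alone
  meta <- trial_meta("s", "forward", "perturbation", 1.7, 0, 2, 30)
  px <- trial2d(meta, list(head = cbind(c(300, 310), c(100, 120)),
                           ankle = cbind(c(300, 300), c(400, 400))),
                90, "pixel")
  m_true <- apply_calibration(map, px)
  map_err <- fit_height_scale(c(320, 60), c(320, 400), 1.80)
  m_err <- apply_calibration(map_err, px)
  ratio <- m_err$markers$head[2, ] / m_true$markers$head[2, ]
  expect_equal(unname(ratio), rep(1.80 / 1.70, 2), tolerance = 1e-9)
  ang_t <- segment_angle_series(m_true$markers$ankle, m_true$markers$head, 30)
  ang_e <- segment_angle_series(m_err$markers$ankle, m_err$markers$head, 30)
  expect_equal(ang_t$values, ang_e$values, tolerance = 1e-9)
})

test_that("calibration application handles units, identity, and pure scale", {
  meta <- trial_meta("c", "forward", "perturbation", 1.7, 0, 2, 30)
  px <- trial2d(meta, list(head = cbind(c(100, 200), c(50, 50))), 90, "pixel")
  ident <- structure(list(kind = "grid2d", H = diag(3),
                          reprojection_rms = 0, provenance = NULL),
                     class = "calibration_mapping")
  out <- apply_calibration(ident, px)
  expect_equal(unname(out$markers$head), unname(px$markers$head))
  expect_error(apply_calibration(ident, out), "already in metre")
  sc <- fit_height_scale(c(0, 0), c(0, 340), 1.70)  # 0.005 m/px
  m <- apply_calibration(sc, px)
  expect_equal(unname(m$markers$head[2, "h"] - m$markers$head[1, "h"]), 0.5)
})

test_that("grid perturbation validates ranges and is absolute", {
  g <- grid_spec()
  expect_identical(perturb_grid(g, 0, 0), g)
  g2 <- perturb_grid(g, 0.2, -15)
  expect_equal(g2$translation, 0.2)
  expect_equal(g2$rotation, -15)
  expect_error(perturb_grid(g, 0.6, 0), "0.5 m")
  expect_error(perturb_grid(g, 0, 50), "45 degree")
})

test_that("grid translation toward the camera shrinks reconstructed lengths", {
  cam <- camera_model(90)
  d <- cam$distance
  tr <- 0.2
  gi <- image_grid(cam, grid_spec(translation = tr), noise_px = 0)
  map <- fit_grid_homography(gi$image, gi$plane)
  # two fall-plane points 1 m apart reconstructed through the biased map
  px <- rbind(project_point(cam, c(-0.5, 0, 0.8)),
              project_point(cam, c(0.5, 0, 0.8)))
  w <- cbind(px, 1) %*% t(map$H)
  w <- w[, 1:2] / w[, 3]
  len <- sqrt(sum((w[2, ] - w[1, ])^2))
  expect_equal(len, (d - tr) / d, tolerance = 1e-3)  # depth-ratio bias
})

test_that("calibration mappings serialize to JSON and back", {
  cam <- camera_model(60)
  gi <- image_grid(cam, grid_spec(), noise_px = 0)
  map <- fit_grid_homography(gi$image, gi$plane)
  js <- calibration_to_json(map)
  back <- calibration_from_json(js)
  expect_equal(back$H, map$H, tolerance = 1e-12, ignore_attr = TRUE)
  hs <- fit_height_scale(c(1, 2), c(1, 300), 1.7, h_sign = -1)
  hs2 <- calibration_from_json(calibration_to_json(hs))
  expect_equal(hs2$scale, hs$scale)
  expect_equal(hs2$h_sign, -1)
})

test_that("height-line and grid calibrations agree at 90 degrees", {
  tr <- simulate_fall("forward", "perturbation", out_of_plane = 0, seed = 3,
                      trial_id = "agree")
  cam <- camera_model(90)
  obs <- observe_with_camera(tr, cam, noise_px = 0, seed = 1)
  gi <- image_grid(cam, grid_spec(), noise_px = 0)
  g_map <- fit_grid_homography(gi$image, gi$plane)
  hl <- height_line_pixels(cam, tr)
  l_map <- fit_height_scale(hl$head_pixel, hl$foot_pixel, 1.70, h_sign = -1)
  mg <- apply_calibration(g_map, obs)
  ml <- apply_calibration(l_map, obs)
  iv <- fall_interval(mg)
  idx <- (iv[1] + 1):iv[2]
  dg <- diff(range(mg$markers$head[idx, "v"]))
  dl <- diff(range(ml$markers$head[idx, "v"]))
  expect_lt(abs(dl - dg) / dg, 0.02)  # vertical displacement within 2%
})
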