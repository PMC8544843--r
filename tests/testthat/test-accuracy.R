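test_that("rmse follows its closed forms and axioms", {
  x <- fs_series(sin((1:100) / 10), 100)
  expect_equal(rmse(x, x), 0)
  y <- fs_series(x$values + 0.25, 100)
  expect_equal(rmse(y, x), 0.25)
  alt <- fs_series(x$values + c(0.3, -0.3), 100)  # alternating +/- e
  expect_equal(rmse(alt, x), 0.3)
  expect_equal(rmse(x, y), rmse(y, x))            # symmetry
  expect_error(rmse(fs_series(1:5, 10), fs_series(1:6, 10)), "lengths")
})

test_that("nrmse normalizes by reference peak-to-peak amplitude", {
  ref <- fs_series(seq(0, 1, length.out = 101), 100)   # 1.0 m span
  test <- fs_series(ref$values + 0.05, 100)
  expect_equal(nrmse(test, ref), 5)
  expect_equal(nrmse(ref, ref), 0)
  # 10% scaled sinusoid over whole periods: 100 * (0.1/sqrt(2)) / 2
  t <- seq(0, 2 - 1 / 100, by = 1 / 100)
  s <- fs_series(sin(2 * pi * t), 100)
  s11 <- fs_series(1.1 * s$values, 100)
  expect_equal(nrmse(s11, s), 100 * 0.1 / sqrt(2) / 2, tolerance = 0.02)
  # invariant to a common additive offset
  expect_equal(nrmse(fs_series(test$values + 3, 100),
                     fs_series(ref$values + 3, 100)), nrmse(test, ref))
  expect_error(nrmse(test, fs_series(rep(1, 101), 100)), "zero-amplitude")
})

test_that("peak differences use the test-minus-reference sign convention", {
  ref <- fs_series(c(0, 3.04, 0), 10)
  test <- fs_series(c(0, 2.86, 0), 10)
  pd <- peak_difference(test, ref)
  expect_equal(pd$raw, -0.18)
  expect_equal(pd$percent, 100 * (-0.18) / 3.04)  # about -5.9%
  expect_equal(pd$abs_raw, 0.18)
  equal <- peak_difference(ref, ref)
  expect_equal(equal$raw, 0)
  expect_equal(equal$percent, 0)
  over <- peak_difference(fs_series(c(0, 3.5, 0), 10), ref)
  expect_gt(over$raw, 0)                           # overestimate -> positive
  # percent invariant to common rescaling
  pd2 <- peak_difference(fs_series(test$values * 7, 10),
                         fs_series(ref$values * 7, 10))
  expect_equal(pd2$percent, pd$percent)
  expect_error(peak_difference(test, fs_series(c(0, 0, 0), 10)), "zero")
})

test_that("linear agreement recovers exact and noisy generative slopes", {
  ref <- c(1.5, 2.1, 2.8, 3.2, 3.9)
  fit <- linear_agreement(ref, ref)
  expect_equal(fit$slope, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$mean_signed_error_pct, 0)
  fit9 <- linear_agreement(0.9 * ref, ref)
  expect_equal(fit9$slope, 0.9)
  expect_equal(fit9$r_squared, 1)
  set.seed(31)
  refn <- runif(200, 1.5, 4)
  testn <- refn + rnorm(200, 0, 0.28)   # sigma chosen for R^2 near 0.9
  fitn <- linear_agreement(testn, refn)
  expect_equal(fitn$slope, 1, tolerance = 0.1)
  expect_gt(fitn$r_squared, 0.8)
  expect_error(linear_agreement(c(1, 2, 3), c(2, 2, 2)), "zero variance")
})

test_that("aggregation reports mean, SE and n per group", {
  rec <- data.frame(grp = c("a", "a", "b"), val = c(4, 6, 5))
  agg <- aggregate_accuracy(rec, "grp")
  expect_equal(agg$val_mean, c(5, 5))
  expect_equal(agg$val_se, c(1, 0))     # single record -> SE 0
  expect_equal(agg$n, c(2, 1))
  # means match a brute-force recomputation on a larger table
  set.seed(8)
  big <- data.frame(g1 = sample(letters[1:3], 60, TRUE),
                    g2 = sample(c("x", "y"), 60, TRUE),
                    m = rnorm(60))
  agg2 <- aggregate_accuracy(big, c("g1", "g2"))
  for (i in seq_len(nrow(agg2))) {
    sub <- big$m[big$g1 == agg2$g1[i] & big$g2 == agg2$g2[i]]
    expect_equal(agg2$m_mean[i], mean(sub))
    expect_equal(agg2$m_se[i], sd(sub) / sqrt(length(sub)))
  }
  expect_error(aggregate_accuracy(rec[0, ], "grp"))
})
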