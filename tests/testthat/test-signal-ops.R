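test_that("dual-pass Butterworth matches the analytic magnitude response", {
  rate <- 200
  t <- seq(0, 10, by = 1 / rate)
  # single-pass 4th-order |H|^2 = 1/(1 + (f/fc)^8); dual pass squares once
  gain <- function(f, fc, order = 4) 1 / (1 + (f / fc)^(2 * order))
  fc <- 10
  for (f in c(fc, fc / 4, fc / 2)) {
    s <- fs_series(sin(2 * pi * f * t), rate)
    out <- lowpass_dualpass(s, fc)
    expect_equal(fit_amplitude(out$values, rate, f), gain(f, fc),
                 tolerance = 0.02)
  }
  # DC gain exactly 1
  const <- lowpass_dualpass(fs_series(rep(2.5, 400), rate), fc)
  expect_equal(const$values, rep(2.5, 400), tolerance = 1e-9)
})

test_that("dual-pass filtering is zero-phase and preserves length", {
  rate <- 100
  t <- seq(0, 6, by = 1 / rate)
  x <- fs_series(sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 5 * t), rate)
  y <- lowpass_dualpass(x, 12)
  expect_length(y$values, length(x$values))
  expect_equal(sync_lag(x, y, max_lag = 0.5), 0)
})

test_that("filtering errors on invalid cutoff or too-short input", {
  s <- fs_series(rnorm(100), 30)
  expect_error(lowpass_dualpass(s, 15), "cutoff")
  expect_error(lowpass_dualpass(s, 20), "cutoff")
  expect_error(lowpass_dualpass(fs_series(rnorm(10), 30), 5), "too short")
})

test_that("cascaded cutoffs behave like the smaller cutoff", {
  rate <- 200
  t <- seq(0, 8, by = 1 / rate)
  set.seed(9)
  x <- lowpass_dualpass(fs_series(rnorm(length(t)), rate), 30)
  a <- lowpass_dualpass(lowpass_dualpass(x, 20), 5)
  b <- lowpass_dualpass(x, 5)
  amp <- diff(range(b$values))
  expect_lt(sqrt(mean((a$values - b$values)^2)), 0.02 * amp)
})

test_that("resampling preserves affine signals, identity, and sinusoids", {
  ramp <- fs_series(3 * (0:30) / 30 + 1, 30)
  up <- resample_to(ramp, 600)
  t_up <- fs_time(up)
  expect_equal(up$values, 3 * t_up + 1, tolerance = 1e-8)
  expect_identical(resample_to(ramp, 30), ramp)
  # original instants reproduced at integer-multiple rates
  expect_equal(up$values[seq(1, length(up$values), by = 20)], ramp$values)
  t30 <- (0:60) / 30
  s <- fs_series(sin(2 * pi * 5 * t30), 30)
  s600 <- resample_to(s, 600)
  truth <- sin(2 * pi * 5 * fs_time(s600))
  expect_lt(sqrt(mean((s600$values - truth)^2)), 0.01)
})

test_that("synchronization recovers constructed lags", {
  rate <- 600
  t <- seq(0, 3, by = 1 / rate)
  set.seed(17)
  base <- lowpass_dualpass(fs_series(rnorm(length(t)), rate), 8)
  expect_equal(sync_lag(base, base, 1), 0)
  k <- as.integer(0.25 * rate)
  delayed <- fs_series(c(rep(base$values[1], k),
                         base$values[1:(length(t) - k)]), rate)
  expect_equal(sync_lag(base, delayed, 1), 0.25, tolerance = 1e-9)
  # noisy shifted copy at SNR 10 recovered within one sample
  set.seed(4)
  noisy <- fs_series(delayed$values +
                       rnorm(length(t), 0, sd(base$values) / sqrt(10)), rate)
  expect_equal(sync_lag(base, noisy, 1), 0.25, tolerance = 1 / rate + 1e-12)
  expect_error(sync_lag(base, fs_series(rep(1, length(t)), rate), 1),
               "zero-variance")
})

test_that("central differences are exact on affine signals", {
  t <- (0:299) / 100
  lin <- central_difference(fs_series(3 * t, 100, unit = "m"))
  expect_equal(lin$values, rep(3, 300), tolerance = 1e-10)
  expect_equal(lin$unit, "m/s")
  expect_equal(central_difference(fs_series(rep(7, 50), 100))$values,
               rep(0, 50))
  expect_error(central_difference(fs_series(c(1, 2), 100)), "3 samples")
})

test_that("central differences match the analytic derivative of a sinusoid", {
  rate <- 600
  t <- seq(0, 2, by = 1 / rate)
  v <- central_difference(fs_series(sin(2 * pi * 2 * t), rate))
  truth <- 4 * pi * cos(2 * pi * 2 * t)
  interior <- 2:(length(t) - 1)
  expect_lt(max(abs(v$values[interior] - truth[interior])) / (4 * pi), 0.001)
})

test_that("central_difference and resample_to commute for band-limited input", {
  t30 <- (0:60) / 30
  s <- fs_series(sin(2 * pi * 1 * t30), 30)
  a <- central_difference(resample_to(s, 600))$values
  b <- resample_to(central_difference(s), 600)$values
  mid <- 50:(length(a) - 50)
  expect_lt(sqrt(mean((a[mid] - b[mid])^2)) / (2 * pi / sqrt(2)), 0.02)
})

test_that("spectral energy fractions follow Parseval on constructed signals", {
  rate <- 600
  t <- seq(0, 2 - 1 / rate, by = 1 / rate)
  expect_equal(energy_fraction_above(fs_series(sin(2 * pi * 5 * t), rate), 20), 0)
  expect_equal(energy_fraction_above(fs_series(sin(2 * pi * 25 * t), rate), 20), 1)
  both <- fs_series(sin(2 * pi * 5 * t) + sin(2 * pi * 25 * t), rate)
  expect_equal(energy_fraction_above(both, 20), 0.5, tolerance = 0.01)
  # complementary bands sum to one
  set.seed(2)
  x <- fs_series(rnorm(512), rate)
  f <- 40
  below <- 1 - energy_fraction_above(x, f)
  expect_equal(energy_fraction_above(x, f) + below, 1)
  expect_warning(res <- energy_fraction_above(x, 300), "Nyquist")
  expect_equal(res, 0)
})
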