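# Lazily built, cached fixtures shared across test files (all generated in
# code; nothing is read from disk).
.fixtures <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# one standard perturbation fall
fx_trial <- function() {
  fx("trial", simulate_fall("forward", "perturbation", seed = 42))
}

# a small mixed batch: one fall per direction x initiation cell
fx_batch <- function() fx("batch", simulate_batch(n_per_cell = 1, seed = 2))

fx_gt <- function() fx("gt", build_ground_truth(fx_batch()))

# amplitude of a sinusoidal component at frequency f in a series
fit_amplitude <- function(values, rate, f, trim = 0.2) {
  n <- length(values)
  keep <- seq(floor(n * trim) + 1L, ceiling(n * (1 - trim)))
  t <- (keep - 1L) / rate
  y <- values[keep]
  a <- 2 * mean(y * sin(2 * pi * f * t))
  b <- 2 * mean(y * cos(2 * pi * f * t))
  sqrt(a^2 + b^2)
}
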