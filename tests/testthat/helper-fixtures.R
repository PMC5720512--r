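# Small, fast study configurations used across the suite. Unit tests run a
# sparse pool (low fibre density, few units) and 3 s signals; the acceptance
# tests use the full study conditions.

small_pool <- function(n_units = 25, fiber_density = 2, ...) {
  pool_params(n_units = n_units, fiber_density = fiber_density, ...)
}

small_config <- function(duration_ms = 3000, ...) {
  simulation_config(pool = small_pool(), duration_ms = duration_ms,
                    n_repeats = 2, ...)
}

# Brownian motion (fBm with Hurst exponent 0.5): cumulative sum of white
# noise; Higuchi dimension 2 - H = 1.5.
brownian_path <- function(n) cumsum(stats::rnorm(n))

expect_monotone_increasing <- function(x, tol = 0) {
  expect_true(all(diff(x) >= -tol * abs(x[-length(x)])),
              label = paste("non-decreasing:", paste(signif(x, 4), collapse = " ")))
}
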