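test_that("MUAP equals brute-force per-fibre SFAP summation", {
  p <- small_pool(n_units = 4)
  pool <- build_pool(p, seed = 5)
  el <- electrode_pair_default(p$muscle_radius + p$cutaneous_mm)
  i <- which.max(pool$n_fibers)
  memb <- attr(pool, "membrane")[[pool$type[i]]]
  m <- muap(pool$fiber_x[[i]], pool$fiber_y[[i]], memb, el, fs = 2000,
            half_length = p$half_length, pennation = p$pennation,
            clip_radius = p$muscle_radius, fiber_z = pool$fiber_z[[i]])
  brute <- rep(0, nrow(m))
  for (f in seq_len(pool$n_fibers[i])) {
    fib <- emg_fiber(origin = c(pool$fiber_x[[i]][f], pool$fiber_y[[i]][f],
                                pool$fiber_z[[i]][f]),
                     half_length = p$half_length, pennation = p$pennation,
                     params = memb)
    w <- sfap(fib, el, fs = 2000, clip_radius = p$muscle_radius,
              duration_ms = nrow(m) / 2)
    brute <- brute + w$voltage[seq_len(nrow(m))]
  }
  expect_equal(m$voltage, brute, tolerance = 1e-10)
})

test_that("MUAP is linear in the fibre set", {
  el <- electrode_pair_default(23)
  x <- c(1, -3, 5); y <- c(2, 8, -4)
  one <- muap(x, y, membrane_params_slow(), el, fs = 1000)
  dup <- muap(c(x, x), c(y, y), membrane_params_slow(), el, fs = 1000)
  expect_equal(dup$voltage, 2 * one$voltage)
  # single-fibre unit reduces to that fibre's SFAP
  single <- muap(2, 15, membrane_params_fast(), el, fs = 1000,
                 pennation = 10, clip_radius = 20)
  fib <- emg_fiber(origin = c(2, 15, 0), pennation = 10,
                   params = membrane_params_fast())
  ref <- sfap(fib, el, fs = 1000, clip_radius = 20,
              duration_ms = nrow(single) + 1)
  expect_equal(single$voltage, ref$voltage[seq_len(nrow(single))],
               tolerance = 1e-10)
})

test_that("composite simulation is deterministic, zero at rest and grows with drive", {
  cfg <- small_config()
  expect_equal(nrow(simulate_semg(cfg, mvc = 25, seed = 1)),
               round(cfg$duration_ms * cfg$fs / 1000))
  z <- simulate_semg(cfg, mvc = 0, seed = 1)
  expect_true(all(z$voltage == 0))
  a <- simulate_semg(cfg, mvc = 50, seed = 3)
  b <- simulate_semg(cfg, mvc = 50, seed = 3)
  expect_identical(a$voltage, b$voltage)
  expect_true(all(is.finite(a$voltage)))

  # higher drive -> larger RMS, checked over 10 seed pairs
  for (s in 1:10) {
    lo <- simulate_semg(cfg, mvc = 25, seed = s)
    hi <- simulate_semg(cfg, mvc = 75, seed = s)
    expect_lt(sqrt(mean(lo$voltage^2)), sqrt(mean(hi$voltage^2)))
  }
})

test_that("composite equals the superposition of per-unit contributions", {
  cfg <- small_config(duration_ms = 2000)
  pool <- build_pool(cfg$pool, seed = 11)
  sig <- simulate_semg(cfg, mvc = 60, seed = 11, pool = pool)

  trains <- generate_spike_trains(pool, drive = 60, duration_ms = 2000,
                                  isi_cv = cfg$isi_cv, seed = 12)
  n_out <- nrow(sig)
  oracle <- numeric(n_out)
  p <- cfg$pool
  for (i in which(lengths(trains$firing_times) > 0)) {
    memb <- attr(pool, "membrane")[[pool$type[i]]]
    tmpl <- muap(pool$fiber_x[[i]], pool$fiber_y[[i]], memb, cfg$electrodes,
                 fs = cfg$fs, half_length = p$half_length,
                 pennation = p$pennation, clip_radius = p$muscle_radius,
                 fiber_z = pool$fiber_z[[i]])$voltage
    for (ft in trains$firing_times[[i]]) {
      s <- round(ft * cfg$fs / 1000) + 1L
      j <- s:min(n_out, s + length(tmpl) - 1L)
      oracle[j] <- oracle[j] + tmpl[seq_along(j)]
    }
  }
  expect_equal(sig$voltage, oracle, tolerance = 1e-12)
})

test_that("drive stationarity: spike counts match the rate law over the trial", {
  pool <- build_pool(small_pool(n_units = 15), seed = 21)
  tr <- generate_spike_trains(pool, drive = 40, duration_ms = 15000, seed = 22)
  for (i in seq_len(nrow(tr))) {
    expected <- tr$rate_hz[i] * 15
    n <- length(tr$firing_times[[i]])
    if (expected == 0) {
      expect_equal(n, 0)
    } else {
      expect_lt(abs(n - expected), 3 * sqrt(expected) + 1)
    }
  }
})

test_that("batch draws stay in their stated ranges and cover the design", {
  cfg <- simulation_config(small_pool(), duration_ms = 3000,
                           mvc_levels = c(25, 50, 75), n_repeats = 3,
                           parameter_ranges = ta_parameter_ranges(125, 250))
  # reduced fibre density keeps this fast; only the draw audit matters here
  cfg$pool$fiber_density <- 2
  b <- semg_batch(cfg, seed = 77)
  expect_equal(nrow(b), 9) # 3 repeats x 3 MVC levels
  expect_equal(sort(unique(b$mvc)), c(25, 50, 75))
  expect_true(all(b$n_units >= 125 & b$n_units <= 250))
  expect_true(all(b$mfr >= 7 & b$mfr <= 23))
  expect_true(all(b$pfr >= 14 & b$pfr <= 50))
  expect_true(all(b$pfr > b$mfr))
  expect_true(all(abs(b$muscle_radius - 20) <= 8))       # mean +/- 4 SD
  expect_true(all(abs(b$velocity_slow - 3.9) <= 1.2))
  expect_true(all(abs(b$velocity_fast - 4.9) <= 1.2))
  expect_true(all(abs(b$half_length - 45) <= 1.6))
  expect_true(all(abs(b$pennation - 20) <= 8))
  # disjoint master seeds give disjoint draws
  b2 <- semg_batch(cfg, seed = 78)
  expect_false(any(b2$muscle_radius %in% b$muscle_radius))
  # signals present and finite
  expect_true(all(purrr::map_lgl(b$signal, ~ all(is.finite(.x$voltage)))))
})

test_that("pennation sweep reports correlations and features per angle", {
  cfg <- small_config()
  sw <- pennation_sweep(cfg, angles = c(0, 10), mvc = 50, seed = 4)
  expect_s3_class(sw, "pennation_sweep")
  expect_equal(sw$angle, c(0, 10))
  expect_equal(sw$correlation[1], 1.0)
  expect_true(all(abs(sw$correlation) <= 1))
  expect_true(all(sw$rms > 0))
  expect_error(pennation_sweep(cfg, angles = c(0, 40)), "\\[0, 30\\]")
})
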