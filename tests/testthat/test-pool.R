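test_that("recruitment thresholds form the exponential ladder", {
  expect_equal(recruitment_thresholds(1, 50), 50)
  expect_equal(recruitment_thresholds(2, 100), c(10, 100))
  rt <- recruitment_thresholds(120, 30)
  expect_equal(rt[120], 30)
  expect_equal(rt[1], exp(log(30) / 120))
  expect_true(all(diff(rt) > 0))
  # geometric: constant successive ratio
  expect_equal(diff(log(rt)), rep(log(30) / 120, 119))
  expect_error(recruitment_thresholds(10, 0), "positive")
})

test_that("firing-rate law runs linearly from MFR at threshold to PFR at full drive", {
  expect_equal(firing_rate(20, 19.99, mfr = 8, pfr = 30), 0)
  expect_equal(firing_rate(20, 20, mfr = 8, pfr = 30), 8)
  rt <- recruitment_thresholds(50, 30)
  expect_equal(firing_rate(rt, 100, mfr = 8, pfr = 30), rep(30, 50))
  # interior point follows mfr + (drive - rt) * (pfr - mfr) / (100 - rt)
  expect_equal(firing_rate(10, 55, mfr = 7, pfr = 37),
               7 + 45 * 30 / 90)
  # degenerate threshold at 100 fires only at exactly 100
  expect_equal(firing_rate(100, 99.9), 0)
  expect_equal(firing_rate(100, 100, mfr = 8, pfr = 30), 30)
  expect_error(firing_rate(10, 120), "\\[0, 100\\]")
})

test_that("rate ordering and monotone recruitment follow the size principle", {
  rt <- recruitment_thresholds(40, 30)
  drives <- seq(0, 100, by = 2.5)
  active_sets <- lapply(drives, function(d) which(rt <= d))
  for (i in seq_along(drives)[-1]) {
    expect_true(all(active_sets[[i - 1]] %in% active_sets[[i]]))
  }
  for (d in drives) {
    fr <- firing_rate(rt, d)
    on <- fr > 0
    if (sum(on) > 1) expect_true(all(diff(fr[on]) <= 1e-12))
  }
  # all units active once the drive reaches the recruitment range
  expect_equal(sum(firing_rate(rt, 30) > 0), 40)
})

test_that("pool construction is deterministic and geometrically contained", {
  p <- small_pool()
  pool1 <- build_pool(p, seed = 9)
  pool2 <- build_pool(p, seed = 9)
  expect_identical(pool1, pool2)
  pool3 <- build_pool(p, seed = 10)
  expect_false(identical(pool1$territory_x, pool3$territory_x))

  # fibre count matches the density-implied budget within rounding
  total <- sum(pool1$n_fibers)
  expect_equal(total, p$fiber_density * pi * p$muscle_radius^2,
               tolerance = 0.02)
  # counts grow with size rank, territories hold their fibres at density
  expect_true(all(diff(pool1$n_fibers) >= 0))
  expect_equal(pool1$territory_radius,
               sqrt(pool1$n_fibers / (pi * p$fiber_density)))
  # containment: all fibre origins inside the muscle disc, territory discs too
  for (i in seq_len(nrow(pool1))) {
    expect_true(all(pool1$fiber_x[[i]]^2 + pool1$fiber_y[[i]]^2 <=
                      p$muscle_radius^2 + 1e-9))
    expect_true(all(abs(pool1$fiber_z[[i]]) <= p$iz_spread_mm + 1e-9))
  }
  centre_r <- sqrt(pool1$territory_x^2 + pool1$territory_y^2)
  expect_true(all(centre_r + pool1$territory_radius <= p$muscle_radius + 1e-9))
  # type assignment respects the slow fraction
  expect_equal(sum(pool1$type == "slow"), round(0.7 * p$n_units))
})

test_that("spike trains respect recruitment, rate and jitter settings", {
  pool <- build_pool(small_pool(), seed = 2)
  # no unit has a threshold of zero, so zero drive silences the pool
  tr0 <- generate_spike_trains(pool, drive = 0, duration_ms = 2000, seed = 1)
  expect_true(all(lengths(tr0$firing_times) == 0))

  # deterministic trains when the ISI jitter is switched off
  trd <- generate_spike_trains(pool, drive = 30, duration_ms = 2000,
                               isi_cv = 0, seed = 3)
  active <- which(lengths(trd$firing_times) > 1)
  for (i in active) {
    isi <- diff(trd$firing_times[[i]])
    expect_equal(isi, rep(1000 / trd$rate_hz[i], length(isi)), tolerance = 1e-9)
    expect_true(all(diff(trd$firing_times[[i]]) > 0))
  }

  # at full drive every unit's empirical rate sits within 3 SE of PFR
  p <- attr(pool, "params")
  tr <- generate_spike_trains(pool, drive = 100, duration_ms = 10000, seed = 4)
  for (i in seq_len(nrow(tr))) {
    n <- length(tr$firing_times[[i]])
    emp <- n / 10
    se <- p$pfr * 0.2 / sqrt(n)
    expect_lt(abs(emp - p$pfr), 3 * se + 0.2) # +0.2 Hz edge-truncation slack
  }
})
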