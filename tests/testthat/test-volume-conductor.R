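test_that("parallel weighting kernel matches the closed form", {
  # direct substitution: source at origin, electrode 10 mm above, isotropic
  expect_equal(weight_parallel(c(0, 0, 0), c(0, 10, 0),
                               sigma_e = 1, sigma_ratio = 1), 1 / (40 * pi))
  # isotropy limit: 1 / (4 pi sigma_e r)
  s <- c(1, -2, 3); e <- c(4, 0, -1)
  r <- sqrt(sum((s - e)^2))
  expect_equal(weight_parallel(s, e, sigma_e = 0.5, sigma_ratio = 1),
               1 / (4 * pi * 0.5 * r))
  # homogeneity of degree -1: doubling all gaps halves the weight
  expect_equal(weight_parallel(2 * s, 2 * e, sigma_e = 0.5, sigma_ratio = 3),
               weight_parallel(s, e, sigma_e = 0.5, sigma_ratio = 3) / 2)
  # reciprocity under source/electrode exchange
  expect_equal(weight_parallel(s, e, sigma_ratio = 5),
               weight_parallel(e, s, sigma_ratio = 5))
  expect_error(weight_parallel(s, s), "singular")
})

test_that("pennate kernel reduces to parallel at zero angle and obeys the rotation oracle", {
  set.seed(7)
  for (i in 1:20) {
    s <- stats::rnorm(3, sd = 10)
    e <- stats::rnorm(3, sd = 10) + c(0, 25, 0)
    expect_equal(weight_pennate(s, e, theta = 0), weight_parallel(s, e))
    th <- stats::runif(1, 0, 30)
    # explicit rotation-matrix oracle: electrode expressed in the fibre frame
    rad <- th * pi / 180
    R <- rbind(c(1, 0, 0),
               c(0, cos(rad), sin(rad)),
               c(0, -sin(rad), cos(rad)))
    expect_equal(weight_pennate(s, e, theta = th),
                 weight_parallel(s, as.numeric(R %*% e)))
  }
  # the rotation moves the source whenever the electrode is off-axis
  expect_false(isTRUE(all.equal(weight_pennate(c(0, 0, 5), c(0, 13, 10), 20),
                                weight_pennate(c(0, 0, 5), c(0, 13, 10), 0))))
  expect_error(weight_pennate(c(0, 0, 0), c(0, 10, 0), theta = 120), "90")
})

test_that("electrode pair enforces its geometry invariants", {
  ep <- electrode_pair_default(13, 10)
  expect_equal(ep$inter_electrode_distance, 10)
  expect_equal(sqrt(sum((ep$contact1 - ep$contact0)^2)),
               ep$inter_electrode_distance, tolerance = 1e-9)
  expect_error(electrode_pair(c(0, 5, 0), c(0, 5, 0)), "distinct")
  expect_error(electrode_pair(c(0, 5, 0), c(0, 10, 0), skin_y = 8), "skin")
  expect_error(emg_fiber(pennation = 45), "\\[0, 30\\]")
  expect_error(emg_fiber(half_length = -1), "positive")
})

test_that("differential SFAP is physically sensible", {
  fib <- emg_fiber()
  el <- electrode_pair_default(13)
  w <- sfap(fib, el, fs = 2000)
  expect_s3_class(w, "sfap_waveform")
  # returns to baseline once the excitation has extinguished
  expect_lt(abs(w$voltage[nrow(w)]), 1e-3 * max(abs(w$voltage)))
  # montage centred over the innervation zone sees mirror-image potentials:
  # the differential waveform cancels
  el0 <- electrode_pair_default(13, 10, z_center_mm = 0)
  w0 <- sfap(fib, el0, fs = 2000)
  expect_lt(max(abs(w0$voltage)), 1e-9 * max(abs(w$voltage)))
  # a fibre at twice the depth has a smaller peak-to-peak amplitude
  deep <- sfap(fib, electrode_pair_default(26), fs = 2000)
  expect_lt(diff(range(deep$voltage)), diff(range(w$voltage)))
  expect_error(sfap(fib, el, fs = 2000, duration_ms = 5), "truncates")
  expect_error(sfap(fib, el, fs = 500), "1000")
})

test_that("SFAP converges under grid refinement and varies continuously with angle", {
  fib <- emg_fiber(pennation = 10)
  el <- electrode_pair_default(13)
  w1 <- sfap(fib, el, fs = 2000, dz_mm = 0.5)
  w2 <- sfap(fib, el, fs = 2000, dz_mm = 0.25)
  rel <- sqrt(sum((w1$voltage - w2$voltage)^2) / sum(w2$voltage^2))
  expect_lt(rel, 0.005)

  # theta-continuity: shrinking the angle step shrinks the waveform change
  d_at <- function(step) {
    a <- sfap(emg_fiber(pennation = 10), el, fs = 2000)
    b <- sfap(emg_fiber(pennation = 10 + step), el, fs = 2000)
    max(abs(a$voltage - b$voltage))
  }
  d1 <- d_at(1); d01 <- d_at(0.1); d001 <- d_at(0.01)
  expect_lt(d01, d1); expect_lt(d001, d01)
  expect_lt(d001, 0.05 * max(abs(sfap(fib, el, fs = 2000)$voltage)))
})

test_that("the truncated sum converges to the charge-conserving waveform in the fibre interior", {
  # integration by parts moves the source's second derivative onto the
  # kernel, so away from the end plate and the fibre ends the two
  # formulations describe the same potential. The truncated integrand is
  # charge-balanced and nearly cancels in the far field, so its midpoint sum
  # converges slowly there; the discrepancy must shrink ~O(dz^2) toward the
  # progressive waveform, which matches the exact integral at any grid.
  fib <- emg_fiber(half_length = 200, params = membrane_params(velocity = 4))
  el <- electrode_pair_default(13)
  wp <- sfap(fib, el, fs = 2000, dz_mm = 0.25, source_model = "progressive")
  wp2 <- sfap(fib, el, fs = 2000, dz_mm = 0.1, source_model = "progressive")
  keep <- wp$time_ms >= 12 & wp$time_ms <= 40
  # the progressive sum is already grid-converged in the interior
  expect_lt(sqrt(sum((wp$voltage[keep] - wp2$voltage[keep])^2) /
                   sum(wp2$voltage[keep]^2)), 1e-3)
  rels <- sapply(c(1, 0.5, 0.25, 0.1), function(dz) {
    wt <- sfap(fib, el, fs = 2000, dz_mm = dz, source_model = "truncated")
    sqrt(sum((wt$voltage[keep] - wp$voltage[keep])^2) / sum(wp$voltage[keep]^2))
  })
  expect_true(all(diff(rels) < 0))
  expect_true(all(rels[-1] / rels[-4] < 0.5))
})

test_that("shape correlation behaves like a Pearson coefficient", {
  w <- sfap(emg_fiber(), electrode_pair_default(13), fs = 2000)
  expect_equal(sfap_shape_correlation(w, w), 1.0)
  neg <- w; neg$voltage <- -neg$voltage
  expect_equal(sfap_shape_correlation(w, neg), -1.0)
  aff <- w; aff$voltage <- 3.2 * aff$voltage + 17
  expect_equal(sfap_shape_correlation(w, aff), 1.0)
  expect_error(sfap_shape_correlation(w$voltage, w$voltage[-1]), "equal length")
  expect_error(sfap_shape_correlation(rep(1, 10), 1:10), "zero-variance")
})
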