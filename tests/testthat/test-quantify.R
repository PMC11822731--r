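test_that("the counting estimator and its Poisson uncertainty are exact", {
  s <- sample_descriptor(1, u_volume_rel = 0, dilution_factor = 1,
                         u_dilution_rel = 0)
  est <- concentration_estimate(100, s)
  expect_equal(est$c_mean, 1e5)
  expect_equal(est$u_rel_combined, 0.10)     # sqrt(100)/100
  expect_equal(unname(est$u_components["counting"]), 0.10)
})

test_that("uncertainty components combine in quadrature", {
  s <- sample_descriptor(rep(1, 4), u_volume_rel = 0.03,
                         dilution_factor = 2, u_dilution_rel = 0.04)
  est <- concentration_estimate(rep(250, 4), s)  # zero scatter -> counting 0
  expect_equal(unname(est$u_components["counting"]), 0)
  expect_equal(est$u_rel_combined, 0.05)
  # Eq-1 scaling: doubling D doubles C; doubling volumes halves C
  s2 <- sample_descriptor(rep(1, 4), 0.03, 4, 0.04)
  expect_equal(concentration_estimate(rep(250, 4), s2)$c_mean, 2 * est$c_mean)
  s3 <- sample_descriptor(rep(2, 4), 0.03, 2, 0.04)
  expect_equal(concentration_estimate(rep(250, 4), s3)$c_mean, est$c_mean / 2)
  # permutation invariance of droplets
  expect_equal(concentration_estimate(c(240, 260, 255, 245), s)$c_mean,
               concentration_estimate(c(255, 245, 260, 240), s)$c_mean)
})

test_that("between-droplet scatter drives the counting term for n >= 3", {
  s <- sample_descriptor(rep(2.5, 7), u_volume_rel = 0, dilution_factor = 1)
  counts <- c(4300, 4450, 4500, 4380, 4470, 4420, 4546)
  est <- concentration_estimate(counts, s)
  expect_equal(unname(est$u_components["counting"]),
               sd(counts) / (mean(counts) * sqrt(7)))
})

test_that("all-zero counts give a flagged upper bound", {
  s <- sample_descriptor(1)
  est <- concentration_estimate(c(0, 0), s)
  expect_true(est$all_zero)
  expect_identical(est$c_mean, 0)
  expect_gt(est$coverage_interval["high"], 0)
  expect_error(concentration_estimate(c(-1, 3), s), "non-negative")
})

test_that("coverage intervals reproduce the reported bounds", {
  ci <- coverage_interval(1.75e13, 0.027, k = 1.96, signif_digits = 3)
  expect_equal(unname(ci), c(1.66e13, 1.84e13))
  expect_equal(unname(coverage_interval(5, 0)), c(5, 5))
  ci1 <- coverage_interval(10, 0.1, k = 1)
  expect_equal(unname(ci1), c(9, 11))
})

test_that("Poisson detection limits have their closed forms", {
  lim <- detection_limits(total_volume_ml = 0.0175)
  expect_equal(lim$lod_count, -log(0.01))
  expect_equal(round(lim$lod_count, 1), 4.6)
  expect_equal(lim$loq_count, 100)
  # concentrations scale with D / V
  lim1 <- detection_limits(1, dilution = 1)
  expect_equal(lim1$lod_conc, -log(0.01))
  lim2 <- detection_limits(0.5, dilution = 1)
  expect_equal(lim2$lod_conc, 2 * lim1$lod_conc)
  lim3 <- detection_limits(1, dilution = 3)
  expect_equal(lim3$loq_conc, 300)
  expect_error(detection_limits(0.0175, confidence = 1), "confidence")
  expect_error(detection_limits(-1), "positive")
})

test_that("the working range balances counting noise against overlaps", {
  wr <- working_range(0.025, total_volume_ml = 0.0175)
  expect_equal(attr(wr, "n_min"), 1600)
  expect_equal(unname(wr["c_min"]), 1600 / 0.0175)
  expect_equal(attr(wr, "rho_max_um2"),
               -log(1 - 0.05) / (pi * 1.2^2))
  # limit behaviour: r_min -> 0 sends c_max to infinity monotonically
  cmaxes <- vapply(c(2, 1, 0.5, 0.25), function(r)
    unname(working_range(0.025, 0.0175, r_min_um = r)["c_max"]), 0)
  expect_true(all(diff(cmaxes) > 0))
  # c_min strictly decreasing in total volume
  cmins <- vapply(c(0.005, 0.01, 0.02), function(v)
    unname(working_range(0.025, v)["c_min"]), 0)
  expect_true(all(diff(cmins) < 0))
  expect_error(working_range(0.5, 0.0175), "0.5")
  # with the study geometry the range brackets ~1e5 to ~1e7-1e8 per mL
  expect_lt(unname(wr["c_min"]), 1.1e5)
  expect_gt(unname(wr["c_max"]), 1e7)
})

test_that("proportional dilution-series fits flag suppressed points", {
  x <- c(1, 2, 5, 10, 20, 50)
  fit <- fit_dilution_series(x, 3 * x)
  expect_equal(fit$slope, 3)
  expect_equal(fit$r_squared, 1)
  expect_true(all(abs(fit$rel_deviation) < 1e-12))
  expect_false(any(fit$out_of_range))
  # a 10% suppressed top point is flagged, the rest are not
  y <- 3 * x; y[6] <- 0.9 * y[6]
  fit2 <- fit_dilution_series(x, y)
  expect_true(fit2$out_of_range[6])
  expect_false(any(fit2$out_of_range[1:5]))
  expect_error(fit_dilution_series(c(1, 2), c(1, 2)), "3 points")
  expect_error(fit_dilution_series(c(1, -2, 3), c(1, 2, 3)), "positive")
})

test_that("gravimetric reference arithmetic and particle masses are exact", {
  expect_equal(signif(gravimetric_reference(11.8, 596), 3), 1.98e13)
  expect_equal(gravimetric_reference(1, 1), 1e15)
  expect_equal(gravimetric_reference(1, 2), gravimetric_reference(1, 1) / 2)
  # sphere: 60 nm core at 4.2 g/cm^3 + 5 nm shell at 2.0 g/cm^3
  m <- particle_mass(60, 5, 4.2, 2.0, shape = "sphere")
  v_core <- 4 / 3 * pi * 30^3
  v_shell <- 4 / 3 * pi * (35^3 - 30^3)
  expect_equal(m, (v_core * 4.2 + v_shell * 2.0) * 1e-3)
  expect_lt(abs(m - 608), 1)
  # dimensional identity: unit-density sphere mass = volume * 1e-3 ag
  expect_equal(particle_mass(2, 0, 1), 4 / 3 * pi * 1e-3)
  # zero shell reduces to the bare core
  expect_equal(particle_mass(60, 0, 4.2, 9), particle_mass(60, 0, 4.2))
  # hexagonal prism has its prism volume
  mh <- particle_mass(10, 0, 1, shape = "hex_prism")
  expect_equal(mh, 3 * sqrt(3) / 2 * 25 * 10 * 1e-3)
})

test_that("method deviation reproduces the cross-method comparison", {
  expect_identical(method_deviation(1.98e13, 1.75e13), 13)
  expect_identical(method_deviation(5, 5), 0)
  expect_identical(method_deviation(10, 5), 100)
})
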