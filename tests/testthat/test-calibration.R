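test_that("EDC drift-time correction follows t_D - C sqrt(mz)/1000", {
  expect_equal(correct_drift_time(5.0, 895.341, 1.41), 4.95781,
               tolerance = 1e-5)
  expect_identical(correct_drift_time(5.0, 1234.5, 0), 5.0)
  expect_error(correct_drift_time(0.01, 895.341, 1.41), "non-positive")
})

test_that("reduced-CCS transform matches direct arithmetic and inverts", {
  # mu = m M / (m + M) with neutral-equivalent m = 896.349 (m/z 895.341)
  m <- 895.341 + 1.007276
  mu <- m * 28.0134 / (m + 28.0134)
  expect_equal(reduced_ccs(290, 895.341, 1), 290 * sqrt(mu),
               tolerance = 1e-9)
  expect_equal(reduced_ccs(290, 895.341, 1), 1511.46, tolerance = 1e-4)
  # round trip exact to 1e-9 relative, both conventions
  for (conv in c("neutral", "ion")) {
    x <- c(150, 290.5, 412.77)
    rt <- inverse_reduced_ccs(
      reduced_ccs(x, 895.341, 2, mass_convention = conv),
      895.341, 2, mass_convention = conv)
    expect_equal(rt, x, tolerance = 1e-9)
  }
  # CCS' decreases with charge at fixed CCS and m/z
  cp <- vapply(1:4, function(z) reduced_ccs(290, 895.341, z), numeric(1))
  expect_true(all(diff(cp) < 0))
})

test_that("TWIMS log-log fit recovers noiseless parameters exactly", {
  g <- synth_calibrants("twims", list(lnA = 5.30, B_exp = 0.550),
                        n_points = 8, noise_rel = 0, seed = 3)
  cal <- fit_twims(g$points)
  expect_equal(cal$lnA, 5.30, tolerance = 1e-9)
  expect_equal(cal$B_exp, 0.550, tolerance = 1e-9)
  expect_equal(cal$r_squared, 1, tolerance = 1e-9)
  # round trip on calibrant points reproduces reference CCS
  ccs_back <- twims_ccs(g$points$t_D, g$points$mz, g$points$z, cal)
  expect_equal(ccs_back, g$points$reference_ccs, tolerance = 1e-9)
  # monotone in drift time
  expect_true(twims_ccs(6, 895.341, 1, cal) >
                twims_ccs(5, 895.341, 1, cal))
  expect_error(fit_twims(g$points[1:2, ]), "at least 3")
})

test_that("TWIMS calibration predicts held-out CCS within 2% under noise", {
  g <- synth_calibrants("twims", list(lnA = 5.30, B_exp = 0.550),
                        n_points = 9, noise_rel = 0.005, seed = 4)
  hold <- 5
  cal <- fit_twims(g$points[-hold, ])
  pred <- twims_ccs(g$points$t_D[hold], g$points$mz[hold],
                    g$points$z[hold], cal)
  expect_lt(abs(pred - g$points$reference_ccs[hold]) /
              g$points$reference_ccs[hold], 0.02)
})

test_that("TIMS linear fit recovers proportional and affine truths", {
  g <- synth_calibrants("tims", list(slope = 1050), n_points = 8,
                        noise_rel = 0, seed = 5)
  cal <- fit_tims(g$points)
  expect_equal(cal$slope, 1050, tolerance = 1e-9)
  expect_identical(cal$intercept, 0)
  # affine truth recovered with a free intercept
  ga <- synth_calibrants("tims", list(slope = 1100, intercept = 40),
                         n_points = 8, noise_rel = 0, seed = 6)
  cala <- fit_tims(ga$points, intercept = "free")
  expect_equal(cala$slope, 1100, tolerance = 1e-6)
  expect_equal(cala$intercept, 40, tolerance = 1e-6)
  # forcing intercept 0 on affine data still returns a fit with residuals
  cal0 <- fit_tims(ga$points, intercept = "zero")
  expect_true(any(abs(cal0$residuals) > 1e-6))
  expect_error(fit_tims(g$points[1, , drop = FALSE]), "at least 2")
})

test_that("TIMS CCS round-trips and is monotone in 1/K0", {
  g <- synth_calibrants("tims", list(slope = 1250), n_points = 8,
                        noise_rel = 0, seed = 7)
  cal <- fit_tims(g$points)
  back <- tims_ccs(g$points$inv_K0, g$points$mz, g$points$z, cal)
  expect_equal(back, g$points$reference_ccs, tolerance = 1e-9)
  expect_true(tims_ccs(1.3, 895.341, 1, cal) >
                tims_ccs(1.2, 895.341, 1, cal))
  # inverse mapping returns the mobility coordinate
  inv <- tims_inv_K0(back, g$points$mz, g$points$z, cal)
  expect_equal(inv, g$points$inv_K0, tolerance = 1e-9)
  # closed-form oracle for a batch of synthetic analytes
  mz <- seq(400, 1600, length.out = 10)
  inv_K0 <- seq(0.8, 1.5, length.out = 10)
  mu <- (mz + 1.007276) * 28.0134 / (mz + 1.007276 + 28.0134)
  expect_equal(tims_ccs(inv_K0, mz, 1, cal),
               cal$slope * inv_K0 / sqrt(mu), tolerance = 1e-9)
})

test_that("cross-instrument %STD matches the two-value formula", {
  r <- cross_instrument_std(290, 292)
  expect_equal(r$per_pair, abs(290 - 292) / sqrt(2) / 291 * 100,
               tolerance = 1e-9)
  expect_equal(r$per_pair, 0.486, tolerance = 1e-3)
  expect_identical(cross_instrument_std(275, 275)$per_pair, 0)
  many <- cross_instrument_std(c(290, 275), c(292, 275))
  expect_equal(many$max, many$per_pair[1])
  # symmetric in its arguments
  expect_equal(cross_instrument_std(292, 290)$per_pair,
               cross_instrument_std(290, 292)$per_pair)
})
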