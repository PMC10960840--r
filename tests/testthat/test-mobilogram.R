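test_that("EIM extraction conserves intensity inside the window", {
  truth <- data.frame(composition = c("Hex2HexNAc2dHex1", "Hex2HexNAc3"),
                      z = 1, centroid = c(1.25, 1.32),
                      sigma = c(0.004, 0.004), abundance = c(1000, 800))
  g <- synth_frame(truth, noise_rel = 0, seed = 1,
                   scan_range = c(1.1, 1.5))
  fr <- g$frame
  eim <- extract_eim(fr, g$truth$mz[1], tol = 0.05)
  in_window <- abs(fr$mz - g$truth$mz[1]) <= 0.05
  expect_equal(sum(eim$intensity), sum(fr$intensity[in_window]),
               tolerance = 1e-12)
  # only the targeted species contributes
  eim2 <- extract_eim(fr, g$truth$mz[2], tol = 0.05)
  expect_gt(sum(eim$intensity), 0)
  expect_true(abs(sum(eim$intensity) + sum(eim2$intensity) -
                    sum(fr$intensity)) < 1e-9)
  # off-target window is empty but flagged, not an error
  none <- extract_eim(fr, 555.5, tol = 0.01)
  expect_true(attr(none, "empty"))
})

test_that("single-Gaussian deconvolution recovers the closed-form area", {
  x <- seq(0.9, 1.1, length.out = 400)
  y <- 100 * exp(-(x - 1.0)^2 / (2 * 0.010^2))
  eim <- structure(data.frame(mobility = x, intensity = y),
                   class = c("eim", "data.frame"))
  attr(eim, "coordinate") <- "inv_K0"; attr(eim, "mz") <- 895.341
  pk <- detect_peaks(eim, max_components = 3)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$centroid, 1.0, tolerance = 1e-6)
  expect_equal(pk$area, 100 * 0.010 * sqrt(2 * pi), tolerance = 1e-6)
  expect_equal(pk$area, 2.50663, tolerance = 1e-4)
})

test_that("well-separated two-component mixtures resolve exactly", {
  x <- seq(1.0, 1.3, length.out = 600)
  # 6 sigma separation, 3:1 area ratio
  y <- 90 * exp(-(x - 1.10)^2 / (2 * 0.008^2)) +
    30 * exp(-(x - 1.148)^2 / (2 * 0.008^2))
  eim <- structure(data.frame(mobility = x, intensity = y),
                   class = c("eim", "data.frame"))
  attr(eim, "coordinate") <- "inv_K0"; attr(eim, "mz") <- 895.341
  pk <- detect_peaks(eim, max_components = 4)
  expect_identical(nrow(pk), 2L)
  truth_areas <- c(90, 30) * 0.008 * sqrt(2 * pi)
  expect_equal(pk$area, truth_areas, tolerance = 1e-6)
  ra <- relative_areas(pk)
  expect_equal(ra$relative_area, c(75, 25), tolerance = 1e-6)
})

test_that("four m/z-895 isomers are recovered at their CCS centroids", {
  cal <- demo_tims_cal()
  ccs_truth <- c(273, 275, 290, 297)
  mz <- glycan_mz(parse_composition("Hex2HexNAc2dHex1"), 1)
  centroids <- tims_inv_K0(ccs_truth, mz, 1, cal)
  sigma_mob <- diff(tims_inv_K0(c(273, 273.6), mz, 1, cal)) * 1
  truth <- data.frame(composition = "Hex2HexNAc2dHex1", z = 1,
                      centroid = centroids, sigma = abs(sigma_mob),
                      abundance = c(30, 20, 30, 20) * 1000)
  g <- synth_frame(truth, noise_rel = 0.01, seed = 42,
                   scan_range = c(1.0, 1.4))
  eim <- extract_eim(g$frame, mz, tol = 0.05)
  pk <- detect_peaks(eim, max_components = 5)
  expect_identical(nrow(pk), 4L)
  pk <- calibrate_peaks(pk, mz, 1, cal)
  expect_true(all(abs(pk$ccs - ccs_truth) < 0.5))
  rel <- relative_areas(pk)$relative_area
  expect_true(all(abs(rel - c(30, 20, 30, 20)) / c(30, 20, 30, 20) < 0.05))
})

test_that("relative areas normalise to 100 and reject degenerate input", {
  pk <- data.frame(area = c(2, 2, 4))
  expect_equal(relative_areas(pk)$relative_area, c(25, 25, 50))
  expect_equal(sum(relative_areas(pk)$relative_area), 100,
               tolerance = 1e-9)
  expect_equal(relative_areas(data.frame(area = 7))$relative_area, 100)
  expect_error(relative_areas(data.frame(area = numeric(0))), "no peaks")
  expect_error(relative_areas(data.frame(area = 0)), "zero total")
})

test_that("charge gating assigns points to non-overlapping bands", {
  bands <- data.frame(z = c(1, 2), intercept = c(0.30, 0.05),
                      slope = c(0.0011, 0.0011), width = c(0.08, 0.08))
  set.seed(9)
  n <- 400L
  z_true <- sample(1:2, n, replace = TRUE)
  mz <- stats::runif(n, 300, 1500)
  mob <- bands$intercept[z_true] + bands$slope[z_true] * mz +
    stats::rnorm(n, 0, 0.02)
  fr <- mobility_frame(mz, mob, rep(1, n), "inv_K0", c(0, 3))
  gated <- charge_gate(fr, bands)
  got1 <- nrow(gated$z1); got2 <- nrow(gated$z2)
  correct <- (got1 + got2 - nrow(gated$unassigned)) >= 0
  # >= 99% of in-band points carry the right label
  lab <- rep(NA, n)
  acc <- (sum(z_true == 1 & mz %in% gated$z1$mz) +
            sum(z_true == 2 & mz %in% gated$z2$mz)) /
    (got1 + got2)
  expect_gte(acc, 0.99)
  expect_identical(got1 + got2 + nrow(gated$unassigned), n)
  # overlapping bands are rejected
  bad <- bands; bad$width <- 0.5
  expect_error(charge_gate(fr, bad), "overlap")
})

test_that("resolving power follows CCS over FWHM", {
  expect_equal(resolving_power(290, 1), 290 / (2 * sqrt(2 * log(2))),
               tolerance = 1e-9)
  expect_equal(resolving_power(290, 1), 123.2, tolerance = 1e-3)
  expect_identical(resolving_power(290, 0), Inf)
  # invariant under uniform CCS rescaling
  expect_equal(resolving_power(2 * 290, 2 * 1), resolving_power(290, 1))
})
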