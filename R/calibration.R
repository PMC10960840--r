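# CCS calibration for travelling-wave (TWIMS) and trapped (TIMS) ion
# mobility spectrometers.
#
# TWIMS drift times are first corrected for the post-mobility flight time
# (EDC delay), then a log-log line relates the corrected drift time to the
# charge- and reduced-mass-corrected CCS' of calibrants of known drift-tube
# CCS (dextran ladder).  TIMS reports reversed mobilities 1/K0, which are
# proportional to CCS' (Mason-Schamp), so a linear fit suffices.

#' EDC delay correction of a TWIMS drift time
#'
#' Subtracts the m/z-dependent travel time from the end of the mobility
#' cell to the mass analyser: t_D' = t_D - C * sqrt(m/z) / 1000.
#'
#' @param t_D Measured drift time (ms).
#' @param mz Ion m/z.
#' @param C EDC delay coefficient (instrument constant, default 1.41).
#' @return Corrected drift time t_D' (ms).
#' @export
#' @examples
#' correct_drift_time(5.0, 895.341)
correct_drift_time <- function(t_D, mz, C = 1.41) {
  out <- t_D - C * sqrt(mz) / 1000
  if (any(out <= 0)) {
    stop("corrected drift time is non-positive: t_D below the EDC delay")
  }
  out
}

.ion_mass <- function(mz, z, mass_convention = c("neutral", "ion")) {
  mass_convention <- match.arg(mass_convention)
  m <- mz * z
  if (mass_convention == "neutral") m <- m + z * mass_constants()[["proton"]]
  m
}

#' Reduced-mass- and charge-corrected CCS
#'
#' CCS' = CCS * sqrt(mu) / z with reduced mass mu = m M / (m + M) for ion
#' mass m and drift-gas molecule mass M.  By default m is taken as the
#' neutral-equivalent mass mz * z + z * 1.007276 (the deprotonation
#' convention used when tabulating glycan CCS); `mass_convention = "ion"`
#' uses the bare deprotonated ion mass mz * z.  The difference is below
#' 0.2 % in sqrt(mu) for glycan-sized ions.
#'
#' @param ccs CCS in A^2.
#' @param mz,z Ion m/z and charge.
#' @param gas_mass Drift-gas molecule mass in Da (default: average N2 mass
#'   28.0134; monoisotopic 28.00615 also common).
#' @param mass_convention `"neutral"` or `"ion"`; see Details.
#' @return CCS' (mass/charge-corrected).
#' @export
#' @examples
#' reduced_ccs(290, mz = 895.341, z = 1)
reduced_ccs <- function(ccs, mz, z = 1L, gas_mass = 28.0134,
                        mass_convention = c("neutral", "ion")) {
  stopifnot(all(ccs > 0))
  m <- .ion_mass(mz, z, mass_convention)
  mu <- m * gas_mass / (m + gas_mass)
  ccs * sqrt(mu) / z
}

#' Invert the reduced-CCS correction
#'
#' @param ccs_prime CCS' value(s).
#' @inheritParams reduced_ccs
#' @return CCS in A^2.
#' @export
inverse_reduced_ccs <- function(ccs_prime, mz, z = 1L, gas_mass = 28.0134,
                                mass_convention = c("neutral", "ion")) {
  m <- .ion_mass(mz, z, mass_convention)
  mu <- m * gas_mass / (m + gas_mass)
  ccs_prime * z / sqrt(mu)
}

.check_calibrants <- function(points, measured_col) {
  need <- c("mz", "z", measured_col, "reference_ccs")
  if (!all(need %in% names(points))) {
    stop("calibrant table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(points$reference_ccs <= 0) || any(points[[measured_col]] <= 0)) {
    stop("calibrant reference CCS and measured values must be positive")
  }
  points
}

#' Fit a TWIMS logarithmic CCS calibration
#'
#' Least-squares fit of ln(CCS') = lnA + B * ln(t_D') over calibrant
#' species of known drift-tube CCS, with t_D' the EDC-corrected drift time
#' and CCS' the reduced-mass/charge-corrected reference CCS.
#'
#' @param points data.frame with columns `mz`, `z`, `t_D` (ms) and
#'   `reference_ccs` (A^2); at least 3 rows.
#' @param edc_C EDC delay coefficient.
#' @param gas_mass Drift-gas molecule mass (Da).
#' @param mass_convention Passed to [reduced_ccs()].
#' @return Object of class `twims_cal` with elements `lnA`, `B_exp`,
#'   `edc_C`, `gas_mass`, `mass_convention`, `r_squared`, `residuals`
#'   (log-space), `points`.
#' @export
fit_twims <- function(points, edc_C = 1.41, gas_mass = 28.0134,
                      mass_convention = c("neutral", "ion")) {
  mass_convention <- match.arg(mass_convention)
  points <- .check_calibrants(as.data.frame(points), "t_D")
  if (nrow(points) < 3) stop("TWIMS calibration needs at least 3 points")
  tdp <- correct_drift_time(points$t_D, points$mz, edc_C)
  if (length(unique(signif(tdp, 12))) < 3) {
    stop("TWIMS calibration needs at least 3 distinct corrected drift times")
  }
  ccsp <- reduced_ccs(points$reference_ccs, points$mz, points$z, gas_mass,
                      mass_convention)
  fit <- stats::lm(log(ccsp) ~ log(tdp))
  structure(
    list(lnA = unname(stats::coef(fit)[1]),
         B_exp = unname(stats::coef(fit)[2]),
         edc_C = edc_C, gas_mass = gas_mass,
         mass_convention = mass_convention,
         r_squared = suppressWarnings(summary(fit)$r.squared),
         residuals = unname(stats::residuals(fit)),
         points = points),
    class = "twims_cal"
  )
}

#' @export
print.twims_cal <- function(x, ...) {
  cat("TWIMS CCS calibration (log-log)\n",
      sprintf("  ln(CCS') = %.6f + %.6f ln(t_D')   R^2 = %.6f\n",
              x$lnA, x$B_exp, x$r_squared),
      sprintf("  EDC C = %.3f, gas mass = %.4f Da, %d calibrants\n",
              x$edc_C, x$gas_mass, nrow(x$points)), sep = "")
  invisible(x)
}

#' CCS of an analyte from a TWIMS calibration
#'
#' @param t_D Drift time(s) in ms.
#' @param mz,z Ion m/z and charge.
#' @param cal A `twims_cal` object.
#' @return CCS in A^2.
#' @export
twims_ccs <- function(t_D, mz, z, cal) {
  stopifnot(inherits(cal, "twims_cal"))
  tdp <- correct_drift_time(t_D, mz, cal$edc_C)
  ccsp <- exp(cal$lnA + cal$B_exp * log(tdp))
  inverse_reduced_ccs(ccsp, mz, z, cal$gas_mass, cal$mass_convention)
}

#' @export
predict.twims_cal <- function(object, t_D, mz, z = 1L, ...) {
  twims_ccs(t_D, mz, z, object)
}

#' Fit a TIMS linear CCS calibration
#'
#' Least-squares fit of CCS' = slope * (1/K0) + intercept over calibrants
#' of known CCS.  By Mason-Schamp proportionality the intercept is fixed
#' at 0 by default; `intercept = "free"` fits an affine line.
#'
#' @param points data.frame with columns `mz`, `z`, `inv_K0` (V s/cm^2)
#'   and `reference_ccs` (A^2); at least 2 rows.
#' @param intercept `"zero"` (default) or `"free"`.
#' @param gas_mass Drift-gas molecule mass (Da).
#' @param mass_convention Passed to [reduced_ccs()].
#' @return Object of class `tims_cal` with elements `slope`, `intercept`,
#'   `gas_mass`, `mass_convention`, `r_squared`, `residuals`, `points`.
#' @export
fit_tims <- function(points, intercept = c("zero", "free"),
                     gas_mass = 28.0134,
                     mass_convention = c("neutral", "ion")) {
  intercept <- match.arg(intercept)
  mass_convention <- match.arg(mass_convention)
  points <- .check_calibrants(as.data.frame(points), "inv_K0")
  if (nrow(points) < 2) stop("TIMS calibration needs at least 2 points")
  ccsp <- reduced_ccs(points$reference_ccs, points$mz, points$z, gas_mass,
                      mass_convention)
  x <- points$inv_K0
  fit <- if (intercept == "zero") stats::lm(ccsp ~ x - 1)
         else stats::lm(ccsp ~ x)
  co <- stats::coef(fit)
  slope <- unname(co[["x"]])
  icpt <- if (intercept == "zero") 0 else unname(co[[1]])
  if (slope <= 0) stop("TIMS calibration slope must be positive")
  ss_tot <- sum((ccsp - mean(ccsp))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(
    list(slope = slope, intercept = icpt, intercept_mode = intercept,
         gas_mass = gas_mass, mass_convention = mass_convention,
         r_squared = r2, residuals = unname(stats::residuals(fit)),
         points = points),
    class = "tims_cal"
  )
}

#' @export
print.tims_cal <- function(x, ...) {
  cat("TIMS CCS calibration (linear in 1/K0)\n",
      sprintf("  CCS' = %.4f * (1/K0) %+.4f   R^2 = %.6f (%s intercept)\n",
              x$slope, x$intercept, x$r_squared, x$intercept_mode),
      sprintf("  gas mass = %.4f Da, %d calibrants\n",
              x$gas_mass, nrow(x$points)), sep = "")
  invisible(x)
}

#' CCS of an analyte from a TIMS calibration
#'
#' @param inv_K0 Reversed mobility 1/K0 (V s/cm^2).
#' @param mz,z Ion m/z and charge.
#' @param cal A `tims_cal` object.
#' @return CCS in A^2.
#' @export
tims_ccs <- function(inv_K0, mz, z, cal) {
  stopifnot(inherits(cal, "tims_cal"))
  ccsp <- cal$slope * inv_K0 + cal$intercept
  inverse_reduced_ccs(ccsp, mz, z, cal$gas_mass, cal$mass_convention)
}

#' @export
predict.tims_cal <- function(object, inv_K0, mz, z = 1L, ...) {
  tims_ccs(inv_K0, mz, z, object)
}

#' Invert a TIMS calibration: 1/K0 expected for a given CCS
#'
#' @param ccs CCS in A^2.
#' @param mz,z Ion m/z and charge.
#' @param cal A `tims_cal` object.
#' @return 1/K0 in V s/cm^2.
#' @export
tims_inv_K0 <- function(ccs, mz, z, cal) {
  stopifnot(inherits(cal, "tims_cal"))
  ccsp <- reduced_ccs(ccs, mz, z, cal$gas_mass, cal$mass_convention)
  (ccsp - cal$intercept) / cal$slope
}

#' Percent standard deviation between paired CCS measurements
#'
#' For each (CCS_a, CCS_b) pair, the two-value sample standard deviation
#' (|a - b| / sqrt(2)) divided by the pair mean, times 100.  Used to
#' compare CCS values of the same structure measured on different
#' instruments.
#'
#' @param ccs_a,ccs_b Positive numeric vectors of equal length.
#' @return List with `per_pair` (numeric vector, %) and `max` (numeric).
#' @export
#' @examples
#' cross_instrument_std(c(290, 275), c(292, 275))
cross_instrument_std <- function(ccs_a, ccs_b) {
  stopifnot(length(ccs_a) == length(ccs_b),
            all(ccs_a > 0), all(ccs_b > 0))
  sd2 <- abs(ccs_a - ccs_b) / sqrt(2)
  pct <- sd2 / ((ccs_a + ccs_b) / 2) * 100
  list(per_pair = pct, max = if (length(pct)) max(pct) else NA_real_)
}
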