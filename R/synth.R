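# Deterministic synthetic-data generators.
#
# Every generator takes an explicit seed, restores the caller's RNG state
# on exit, and returns its ground truth alongside the data so downstream
# recovery can be checked against the truth rather than re-derived.
# The intensity noise model is multiplicative log-normal (the usual
# heteroscedastic behaviour of MS intensities): I = I0 * exp(e),
# e ~ N(0, noise_rel), so noise_rel ~ relative sd for small levels.

.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L) {
    stop("a single integer seed is required")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Simulate an ion-mobility frame from a truth table
#'
#' Each truth record contributes a Gaussian mobility profile at the
#' theoretical m/z of its composition (deprotonated, its charge), sampled
#' on a regular mobility grid, with multiplicative log-normal intensity
#' noise.  Mimics an accumulated direct-infusion TIMS (or TWIMS) frame.
#'
#' @param truth data.frame with columns `composition` (canonical string),
#'   `z`, `centroid` (mobility coordinate), `sigma`, `abundance` (total
#'   area), optional `sample`.
#' @param noise_rel Relative intensity noise level (0 = noiseless).
#' @param seed Integer seed (mandatory).
#' @param coordinate Mobility coordinate kind.
#' @param scan_range Mobility scan limits.
#' @param n_grid Grid points across the scan range.
#' @return List with `frame` (a [mobility_frame()]) and `truth` (the input
#'   with an `mz` column added).
#' @export
synth_frame <- function(truth, noise_rel = 0, seed,
                        coordinate = c("inv_K0", "t_D"),
                        scan_range = c(0.6, 1.6), n_grid = 1000) {
  coordinate <- match.arg(coordinate)
  stopifnot(all(c("composition", "z", "centroid", "sigma", "abundance")
                %in% names(truth)))
  if (any(truth$abundance <= 0)) stop("truth abundances must be positive")
  if (any(truth$centroid < scan_range[1] | truth$centroid > scan_range[2])) {
    stop("truth centroids must lie within the scan range")
  }
  truth$mz <- vapply(seq_len(nrow(truth)), function(i) {
    glycan_mz(parse_composition(truth$composition[i]), truth$z[i])
  }, numeric(1))
  grid <- seq(scan_range[1], scan_range[2], length.out = n_grid)
  dx <- grid[2] - grid[1]
  .with_seed(seed, {
    parts <- lapply(seq_len(nrow(truth)), function(i) {
      y <- truth$abundance[i] * dx *
        stats::dnorm(grid, truth$centroid[i], truth$sigma[i])
      if (noise_rel > 0) y <- y * exp(stats::rnorm(length(y), 0, noise_rel))
      data.frame(mz = truth$mz[i], mobility = grid, intensity = y)
    })
    d <- do.call(rbind, parts)
    d <- d[d$intensity > 0, , drop = FALSE]
    list(frame = mobility_frame(d$mz, d$mobility, d$intensity,
                                coordinate, scan_range),
         truth = truth)
  })
}

#' Simulate a negative-mode CID peak list for a structure
#'
#' Fragment m/z values come from [generate_fragments()]; intensities are
#' unit height with multiplicative log-normal noise, and peaks are
#' randomly dropped at the given rate (emulating low-abundance fragments
#' falling below the detection threshold).
#'
#' @param structure_text Condensed structure string.
#' @param kinds Fragment kinds, see [generate_fragments()].
#' @param noise_rel Relative intensity noise.
#' @param dropout Fraction of fragments dropped (0..1).
#' @param seed Integer seed (mandatory).
#' @param max_cleavages Passed to [generate_fragments()].
#' @return List with `peaks` (data.frame `mz`, `intensity`) and `truth`
#'   (the full fragment table).
#' @export
synth_spectrum <- function(structure_text,
                           kinds = c("B", "C", "Y", "Z", "A"),
                           noise_rel = 0, dropout = 0, seed,
                           max_cleavages = 1L) {
  s <- parse_structure(structure_text)
  frags <- generate_fragments(s, kinds = kinds,
                              max_cleavages = max_cleavages)
  .with_seed(seed, {
    n <- nrow(frags)
    keep <- if (dropout > 0) stats::runif(n) >= dropout else rep(TRUE, n)
    intensity <- rep(1, n)
    if (noise_rel > 0) {
      intensity <- intensity * exp(stats::rnorm(n, 0, noise_rel))
    }
    peaks <- data.frame(mz = frags$mz[keep], intensity = intensity[keep])
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
    list(peaks = peaks, truth = frags)
  })
}

# dextran ladder (glucose oligomer alditol-free) [M - H]- m/z values
.dextran_mz <- function(n_units) {
  k <- mass_constants()
  (n_units * residue_mass("Hex") + k[["water"]] - k[["proton"]])
}

#' Simulate calibrant measurements for TWIMS or TIMS
#'
#' Generates a dextran-like calibrant ladder (Hex_n oligomers, n = 2, 3,
#' ...), assigns each a reference CCS from a smooth size law
#' (CCS = 9.5 * sqrt(m), the square-root size growth typical of compact
#' carbohydrate ions in nitrogen, anchored near 285 A^2 at 900 Da), and
#' produces measured drift times (TWIMS, from the
#' forward log-log model with parameters `true_params$lnA`,
#' `true_params$B_exp`) or reversed mobilities (TIMS, from
#' `true_params$slope`, `true_params$intercept`), with multiplicative
#' noise on the measured coordinate.
#'
#' @param mode `"twims"` or `"tims"`.
#' @param true_params Named list of forward-model parameters (see above).
#' @param n_points Number of calibrant species (>= 3).
#' @param noise_rel Relative noise on the measured coordinate.
#' @param seed Integer seed (mandatory).
#' @param edc_C,gas_mass,mass_convention Conventions used in the forward
#'   model, matching the fit functions' defaults.
#' @return List with `points` (calibrant data.frame ready for
#'   [fit_twims()]/[fit_tims()]) and `truth` (`true_params`).
#' @export
synth_calibrants <- function(mode = c("twims", "tims"), true_params,
                             n_points = 8, noise_rel = 0, seed,
                             edc_C = 1.41, gas_mass = 28.0134,
                             mass_convention = "neutral") {
  mode <- match.arg(mode)
  if (n_points < 3) stop("at least 3 calibrant species are required")
  units <- seq(2, length.out = n_points)
  mz <- .dextran_mz(units)
  z <- rep(1L, n_points)
  mass <- mz + mass_constants()[["proton"]]
  ccs <- 9.5 * sqrt(mass)
  ccsp <- reduced_ccs(ccs, mz, z, gas_mass, mass_convention)
  .with_seed(seed, {
    if (mode == "twims") {
      tdp <- exp((log(ccsp) - true_params$lnA) / true_params$B_exp)
      t_D <- tdp + edc_C * sqrt(mz) / 1000
      if (noise_rel > 0) {
        t_D <- t_D * exp(stats::rnorm(n_points, 0, noise_rel))
      }
      pts <- data.frame(species = paste0("Hex", units), mz = mz, z = z,
                        t_D = t_D, reference_ccs = ccs)
    } else {
      icpt <- if (is.null(true_params$intercept)) 0
              else true_params$intercept
      inv_K0 <- (ccsp - icpt) / true_params$slope
      if (noise_rel > 0) {
        inv_K0 <- inv_K0 * exp(stats::rnorm(n_points, 0, noise_rel))
      }
      pts <- data.frame(species = paste0("Hex", units), mz = mz, z = z,
                        inv_K0 = inv_K0, reference_ccs = ccs)
    }
    list(points = pts, truth = true_params)
  })
}

#' Read a calibrant table from CSV
#'
#' Columns: `species`, `mz`, `z`, `measured`, `reference_ccs`.  The
#' `measured` column is renamed to `t_D` (mode `"twims"`) or `inv_K0`
#' (mode `"tims"`) for the fit functions.
#'
#' @param path CSV path.
#' @param mode `"twims"` or `"tims"`.
#' @return data.frame ready for [fit_twims()] or [fit_tims()].
#' @export
read_calibrants_csv <- function(path, mode = c("twims", "tims")) {
  mode <- match.arg(mode)
  d <- utils::read.csv(path)
  need <- c("species", "mz", "z", "measured", "reference_ccs")
  if (!all(need %in% names(d))) {
    stop("calibrant CSV must have columns: ", paste(need, collapse = ", "))
  }
  names(d)[names(d) == "measured"] <- if (mode == "twims") "t_D"
                                      else "inv_K0"
  d
}
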