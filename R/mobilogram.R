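# Extracted ion mobilograms and Gaussian deconvolution.
#
# A mobility frame is the accumulated (m/z, mobility, intensity) point
# cloud of a direct-infusion IMS-MS acquisition.  Extracting a narrow m/z
# window gives the mobilogram of one composition, whose overlapping
# Gaussian components are the isomers; their fitted areas quantify isomer
# ratios.

#' Construct a mobility frame
#'
#' @param mz,mobility,intensity Equal-length numeric vectors; intensities
#'   must be non-negative.
#' @param coordinate `"inv_K0"` (TIMS, V s/cm^2) or `"t_D"` (TWIMS, ms).
#' @param scan_range Length-2 numeric, mobility scan limits.
#' @return Object of class `mobility_frame` (a data.frame with metadata
#'   attributes).
#' @export
mobility_frame <- function(mz, mobility, intensity,
                           coordinate = c("inv_K0", "t_D"),
                           scan_range = range(mobility)) {
  coordinate <- match.arg(coordinate)
  stopifnot(length(mz) == length(mobility),
            length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be non-negative")
  out <- data.frame(mz = mz, mobility = mobility, intensity = intensity)
  attr(out, "coordinate") <- coordinate
  attr(out, "scan_range") <- as.numeric(scan_range)
  class(out) <- c("mobility_frame", "data.frame")
  out
}

#' Read a mobility frame from a CSV of (mz, mobility, intensity) triples
#'
#' @param path CSV file with columns `mz`, `mobility`, `intensity`.
#' @param coordinate Mobility coordinate kind of the file.
#' @return A `mobility_frame`.
#' @export
read_frame_csv <- function(path, coordinate = c("inv_K0", "t_D")) {
  d <- utils::read.csv(path)
  need <- c("mz", "mobility", "intensity")
  if (!all(need %in% names(d))) {
    stop("frame CSV must have columns: ", paste(need, collapse = ", "))
  }
  mobility_frame(d$mz, d$mobility, d$intensity, match.arg(coordinate))
}

#' Write a mobility frame to CSV
#' @param frame A `mobility_frame`.
#' @param path Output path.
#' @export
write_frame_csv <- function(frame, path) {
  utils::write.csv(as.data.frame(frame)[c("mz", "mobility", "intensity")],
                   path, row.names = FALSE)
}

#' Read a mobility frame from an mzML file with ion-mobility arrays
#'
#' Best-effort reader over `mzR` for converted instrument files that store
#' an inverse-reduced-mobility array per spectrum.  Requires the `mzR`
#' package; plain CSV triples via [read_frame_csv()] are the portable
#' route.
#'
#' @param path mzML file.
#' @param coordinate Mobility coordinate kind.
#' @return A `mobility_frame`.
#' @export
read_frame_mzml <- function(path, coordinate = c("inv_K0", "t_D")) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package; use read_frame_csv() for ",
         "tabular input")
  }
  coordinate <- match.arg(coordinate)
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  n <- nrow(hdr)
  mob_col <- intersect(c("ionMobilityDriftTime", "inverseK0"), names(hdr))
  parts <- vector("list", n)
  for (i in seq_len(n)) {
    pk <- mzR::peaks(handle, i)
    mob <- if (length(mob_col)) hdr[[mob_col[1]]][i] else NA_real_
    parts[[i]] <- data.frame(mz = pk[, 1], mobility = mob,
                             intensity = pk[, 2])
  }
  d <- do.call(rbind, parts)
  d <- d[!is.na(d$mobility), , drop = FALSE]
  mobility_frame(d$mz, d$mobility, d$intensity, coordinate)
}

#' Extract an ion mobilogram for one m/z window
#'
#' Sums intensity over all frame points within the m/z tolerance, binned
#' on a mobility grid.  When the frame's native mobility values form a
#' modest set of distinct grid points, that native grid is reused;
#' otherwise `n_bins` fixed-width bins span the scan range.
#'
#' @param frame A `mobility_frame`.
#' @param mz Target m/z.
#' @param tol Window half-width; absolute m/z by default.
#' @param tol_unit `"mz"` or `"ppm"`.
#' @param n_bins Grid size when re-binning is needed.
#' @return Object of class `eim`: data.frame of `mobility`, `intensity`
#'   with attributes `mz`, `tol`, `coordinate`, `empty`.
#' @export
extract_eim <- function(frame, mz, tol = 0.05, tol_unit = c("mz", "ppm"),
                        n_bins = 1000) {
  stopifnot(inherits(frame, "mobility_frame"), tol > 0)
  tol_unit <- match.arg(tol_unit)
  half <- if (tol_unit == "ppm") mz * tol / 1e6 else tol
  sel <- abs(frame$mz - mz) <= half
  sub <- frame[sel, , drop = FALSE]
  native <- sort(unique(frame$mobility))
  use_native <- length(native) <= 8192
  if (use_native) {
    grid <- native
    intensity <- numeric(length(grid))
    if (nrow(sub)) {
      idx <- match(sub$mobility, grid)
      agg <- tapply(sub$intensity, idx, sum)
      intensity[as.integer(names(agg))] <- as.numeric(agg)
    }
  } else {
    rng <- attr(frame, "scan_range")
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    grid <- (edges[-1] + edges[-length(edges)]) / 2
    intensity <- numeric(n_bins)
    if (nrow(sub)) {
      idx <- pmin(pmax(findInterval(sub$mobility, edges,
                                    rightmost.closed = TRUE), 1L), n_bins)
      agg <- tapply(sub$intensity, idx, sum)
      intensity[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  out <- data.frame(mobility = grid, intensity = intensity)
  attr(out, "mz") <- mz
  attr(out, "tol") <- half
  attr(out, "coordinate") <- attr(frame, "coordinate")
  attr(out, "empty") <- !any(intensity > 0)
  class(out) <- c("eim", "data.frame")
  out
}

.gauss_mix <- function(x, par) {
  k <- length(par) / 3
  y <- 0
  for (i in seq_len(k)) {
    a <- par[3 * i - 2]; m <- par[3 * i - 1]; s <- par[3 * i]
    y <- y + a * exp(-(x - m)^2 / (2 * s^2))
  }
  y
}

.seed_centroids <- function(x, y, k, sg_window) {
  ys <- y
  if (length(y) >= sg_window && sg_window >= 5) {
    ys <- signal::sgolayfilt(y, p = 3, n = sg_window)
  }
  # local maxima of the smoothed trace
  n <- length(ys)
  is_max <- c(FALSE, ys[2:(n - 1)] > ys[1:(n - 2)] &
                ys[2:(n - 1)] >= ys[3:n], FALSE)
  cand <- which(is_max & ys > 0.02 * max(ys))
  cand <- cand[order(-ys[cand])]
  cand[seq_len(min(k, length(cand)))]
}

#' Deconvolve an extracted ion mobilogram into Gaussian components
#'
#' Fits mixtures of 1..`max_components` Gaussians by Levenberg-Marquardt
#' nonlinear least squares, selects the component count by the Bayesian
#' information criterion, and discards components whose amplitude falls
#' below `min_snr` times the noise level (median absolute deviation of
#' the fit residuals).  Starting centroids come from peak-picking on a
#' Savitzky-Golay-smoothed trace; additional seeds are placed at the
#' largest fit residual, so the procedure is deterministic.
#'
#' @param eim An `eim` from [extract_eim()].
#' @param max_components Maximum number of Gaussians (>= 1).
#' @param min_snr Amplitude/noise cutoff for reporting a component.
#' @param sg_window Odd smoothing window length (grid points).
#' @return Object of class `mobility_peaks`: data.frame with columns
#'   `centroid`, `sigma`, `amplitude`, `area` (= amplitude * sigma *
#'   sqrt(2*pi)), sorted by centroid; attributes `k`, `bic`, `noise`,
#'   `coordinate`, `mz`.
#' @export
detect_peaks <- function(eim, max_components = 4L, min_snr = 3,
                         sg_window = 9L) {
  stopifnot(inherits(eim, "eim"), max_components >= 1)
  x <- eim$mobility
  y <- eim$intensity
  if (!any(y > 0)) stop("empty mobilogram: nothing to fit")
  n <- length(x)
  fits <- list()
  for (k in seq_len(max_components)) {
    seeds <- .seed_centroids(x, y, k, sg_window)
    start <- numeric(0)
    span <- diff(range(x))
    s0 <- span / 30
    prev <- if (k > 1 && length(fits) >= k - 1 && !is.null(fits[[k - 1]]))
      fits[[k - 1]]$par else NULL
    if (!is.null(prev)) {
      start <- prev
      # place the extra component at the largest residual
      res <- y - .gauss_mix(x, prev)
      j <- which.max(res)
      start <- c(start, max(res[j], 0.05 * max(y)), x[j], s0)
    } else {
      for (i in seq_len(k)) {
        idx <- if (i <= length(seeds)) seeds[i] else which.max(y)
        start <- c(start, y[idx], x[idx], s0)
      }
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start,
        fn = function(p) y - .gauss_mix(x, p),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) { fits[[k]] <- NULL; next }
    rss <- sum(fit$fvec^2)
    bic <- n * log(max(rss, 1e-300) / n) + (3 * k) * log(n)
    fits[[k]] <- list(par = fit$par, rss = rss, bic = bic, k = k)
    if (rss / sum(y^2) < 1e-18) break  # numerically perfect fit
  }
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    stop("mobilogram deconvolution failed to converge for any ",
         "component count")
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]
  par <- best$par
  k <- best$k
  amp <- par[seq(1, 3 * k, 3)]
  cen <- par[seq(2, 3 * k, 3)]
  sig <- abs(par[seq(3, 3 * k, 3)])
  resid <- y - .gauss_mix(x, par)
  noise <- stats::mad(resid)
  keep <- amp > min_snr * noise & amp > 0 & sig > 0 &
    cen >= min(x) & cen <= max(x)
  out <- data.frame(centroid = cen[keep], sigma = sig[keep],
                    amplitude = amp[keep])
  out$area <- out$amplitude * out$sigma * sqrt(2 * pi)
  out <- out[order(out$centroid), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k") <- best$k
  attr(out, "bic") <- best$bic
  attr(out, "noise") <- noise
  attr(out, "coordinate") <- attr(eim, "coordinate")
  attr(out, "mz") <- attr(eim, "mz")
  class(out) <- c("mobility_peaks", "data.frame")
  out
}

#' Annotate relative areas of isomer peaks
#'
#' Relative area of each component in percent of the summed area of all
#' components at the same m/z (the convention used to annotate isomer
#' abundances on mobilograms).
#'
#' @param peaks A `mobility_peaks` data.frame (or any data.frame with an
#'   `area` column).
#' @return The input with a `relative_area` column; percentages sum to 100.
#' @export
relative_areas <- function(peaks) {
  if (nrow(peaks) < 1) stop("no peaks to normalise")
  total <- sum(peaks$area)
  if (total <= 0) stop("zero total area")
  peaks$relative_area <- 100 * peaks$area / total
  peaks
}

#' Convert fitted mobility peaks to CCS space
#'
#' Maps centroid and width through a calibration.  For TIMS the mapping is
#' linear in 1/K0 so the width converts exactly; for TWIMS the local
#' derivative is used.
#'
#' @param peaks A `mobility_peaks` object.
#' @param mz,z Precursor m/z and charge.
#' @param cal A `tims_cal` or `twims_cal`.
#' @return The input with columns `ccs` and `sigma_ccs` added.
#' @export
calibrate_peaks <- function(peaks, mz, z, cal) {
  f <- if (inherits(cal, "tims_cal")) {
    function(v) tims_ccs(v, mz, z, cal)
  } else if (inherits(cal, "twims_cal")) {
    function(v) twims_ccs(v, mz, z, cal)
  } else stop("cal must be a tims_cal or twims_cal")
  peaks$ccs <- f(peaks$centroid)
  up <- f(peaks$centroid + peaks$sigma)
  dn <- f(peaks$centroid - peaks$sigma)
  peaks$sigma_ccs <- abs(up - dn) / 2
  peaks
}

#' Mobility resolving power of a calibrated peak
#'
#' CCS / FWHM with FWHM = 2 sqrt(2 ln 2) * sigma_CCS.  Infinite for
#' vanishing width.
#'
#' @param ccs Peak CCS (A^2).
#' @param sigma_ccs Gaussian sigma in CCS space (A^2).
#' @return Resolving power (dimensionless).
#' @export
resolving_power <- function(ccs, sigma_ccs) {
  fwhm <- 2 * sqrt(2 * log(2)) * sigma_ccs
  ifelse(fwhm == 0, Inf, ccs / fwhm)
}

#' Split a frame into charge-state subsets using mobility trendlines
#'
#' In an m/z vs mobility heatmap the charge states fall on distinct
#' trendlines.  Bands are given as linear center lines with a half-width:
#' a point belongs to charge z when |mobility - (intercept + slope * mz)|
#' <= width.  Bands must not overlap at any observed m/z.
#'
#' @param frame A `mobility_frame`.
#' @param bands data.frame with columns `z`, `intercept`, `slope`, `width`.
#' @return List with one `mobility_frame` per charge (named `"z1"`, ...)
#'   plus `"unassigned"`.
#' @export
charge_gate <- function(frame, bands) {
  stopifnot(inherits(frame, "mobility_frame"))
  need <- c("z", "intercept", "slope", "width")
  if (!all(need %in% names(bands))) {
    stop("bands must have columns: ", paste(need, collapse = ", "))
  }
  centers <- outer(bands$intercept, rep(1, nrow(frame))) +
    outer(bands$slope, frame$mz)
  inside <- abs(t(centers) - matrix(frame$mobility, nrow(frame),
                                    nrow(bands))) <=
    matrix(bands$width, nrow(frame), nrow(bands), byrow = TRUE)
  if (any(rowSums(inside) > 1)) {
    stop("charge bands overlap at some observed m/z")
  }
  lab <- rep(NA_integer_, nrow(frame))
  for (j in seq_len(nrow(bands))) lab[inside[, j]] <- bands$z[j]
  split_frame <- function(sel) {
    mobility_frame(frame$mz[sel], frame$mobility[sel], frame$intensity[sel],
                   attr(frame, "coordinate"), attr(frame, "scan_range"))
  }
  out <- lapply(bands$z, function(zz) split_frame(!is.na(lab) & lab == zz))
  names(out) <- paste0("z", bands$z)
  out$unassigned <- split_frame(is.na(lab))
  out
}
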