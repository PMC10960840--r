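# Sample-level glycosylation summaries.
#
# A profile collects the assigned mobility peaks of one sample (m/z, CCS,
# area, composition, core label, motif flags).  Core and feature
# abundances are expressed as percentages of summed mobility peak area,
# the representation used to compare mucin O-glycosylation between
# samples (e.g. healthy vs cystic fibrosis sputum).

#' Construct a glycosylation profile
#'
#' @param sample Sample identifier.
#' @param peaks data.frame with at least `mz`, `area` and `core`
#'   (character, `"core1"` ... `"core8"` or `"unassigned"`); optional
#'   columns `ccs`, `composition`, `structure`, and logical feature flags
#'   `sialylated`, `fucosylated`, `sulfated`.  Missing feature flags are
#'   derived from `composition` strings when present.
#' @return Object of class `glyco_profile`.
#' @export
glyco_profile <- function(sample, peaks) {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) == 0) stop("empty profile: no peaks")
  if (!all(c("mz", "area", "core") %in% names(peaks))) {
    stop("profile peaks need columns mz, area, core")
  }
  if (any(peaks$area < 0) || sum(peaks$area) <= 0) {
    stop("peak areas must be non-negative with positive total")
  }
  for (flag in c("sialylated", "fucosylated", "sulfated")) {
    if (is.null(peaks[[flag]])) {
      if (!is.null(peaks$composition)) {
        comps <- lapply(peaks$composition, parse_composition)
        peaks[[flag]] <- vapply(comps, function(cc) {
          switch(flag,
                 sialylated  = cc$counts[["NeuAc"]] > 0,
                 fucosylated = cc$counts[["dHex"]] > 0,
                 sulfated    = cc$sulfate > 0)
        }, logical(1))
      } else {
        peaks[[flag]] <- FALSE
      }
    }
  }
  structure(list(sample = sample, peaks = peaks,
                 total_area = sum(peaks$area)),
            class = "glyco_profile")
}

#' @export
print.glyco_profile <- function(x, ...) {
  cat("<glyco_profile> sample ", x$sample, ": ", nrow(x$peaks),
      " peaks, total area ", format(x$total_area), "\n", sep = "")
  invisible(x)
}

#' Relative area per O-glycan core
#'
#' @param p A `glyco_profile`.
#' @param cores Core labels reported individually; everything else
#'   (rarer cores 5-8 and unassigned structures) is folded into
#'   `"other"` unless `collapse_other = FALSE`.
#' @param collapse_other Fold non-listed labels into `"other"`?
#' @return Named numeric vector of percentages summing to 100.
#' @export
group_by_core <- function(p, cores = paste0("core", 1:4),
                          collapse_other = TRUE) {
  stopifnot(inherits(p, "glyco_profile"))
  lab <- p$peaks$core
  if (collapse_other) lab[!lab %in% cores] <- "other"
  agg <- tapply(p$peaks$area, lab, sum)
  levels <- if (collapse_other) c(cores, "other") else sort(unique(lab))
  out <- stats::setNames(numeric(length(levels)), levels)
  out[names(agg)] <- as.numeric(agg)
  100 * out / p$total_area
}

#' Relative area carrying each glycosylation feature
#'
#' Percent of total mobility area carried by sialylated (Neu5Ac),
#' fucosylated (Fuc) and sulfated (S) structures.  A peak carrying several
#' features counts once in each group, so the three percentages need not
#' sum to 100.
#'
#' @param p A `glyco_profile`.
#' @return Named numeric vector (`sialylated`, `fucosylated`, `sulfated`),
#'   each in \[0, 100\].
#' @export
group_by_feature <- function(p) {
  stopifnot(inherits(p, "glyco_profile"))
  vapply(c(sialylated = "sialylated", fucosylated = "fucosylated",
           sulfated = "sulfated"), function(flag) {
    100 * sum(p$peaks$area[p$peaks[[flag]]]) / p$total_area
  }, numeric(1))
}

#' Compare isomer abundance ratios between two samples
#'
#' For each requested m/z, the isomer peaks of both profiles (matched by
#' increasing CCS/mobility order) are expressed as relative areas within
#' their own sample, and the rank order of isomer abundance is compared:
#' a reversal of rank order between samples (e.g. 75/25 becoming 25/75)
#' is flagged as an inversion.
#'
#' @param a,b `glyco_profile` objects.
#' @param mz_list Numeric vector of precursor m/z values to compare.
#' @param tol Absolute m/z half-window for selecting peaks.
#' @return data.frame with one row per (m/z, isomer index): columns `mz`,
#'   `isomer`, `ccs_a`, `rel_area_a`, `ccs_b`, `rel_area_b`, `missing`
#'   and `inversion` (flag on every row of an inverted m/z group).
#' @export
isomer_ratio_table <- function(a, b, mz_list, tol = 0.3) {
  stopifnot(inherits(a, "glyco_profile"), inherits(b, "glyco_profile"))
  rows <- list()
  for (mz in mz_list) {
    pa <- a$peaks[abs(a$peaks$mz - mz) <= tol, , drop = FALSE]
    pb <- b$peaks[abs(b$peaks$mz - mz) <= tol, , drop = FALSE]
    ord <- function(d) {
      key <- if (!is.null(d$ccs) && !anyNA(d$ccs)) d$ccs else d$area
      d[order(key), , drop = FALSE]
    }
    if (nrow(pa) == 0 || nrow(pb) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        mz = mz, isomer = NA_integer_, ccs_a = NA_real_,
        rel_area_a = NA_real_, ccs_b = NA_real_, rel_area_b = NA_real_,
        missing = TRUE, inversion = FALSE)
      next
    }
    pa <- ord(pa); pb <- ord(pb)
    ra <- 100 * pa$area / sum(pa$area)
    rb <- 100 * pb$area / sum(pb$area)
    n <- min(nrow(pa), nrow(pb))
    inv <- n >= 2 &&
      !identical(order(ra[seq_len(n)]), order(rb[seq_len(n)]))
    for (i in seq_len(max(nrow(pa), nrow(pb)))) {
      rows[[length(rows) + 1]] <- data.frame(
        mz = mz, isomer = i,
        ccs_a = if (i <= nrow(pa) && !is.null(pa$ccs)) pa$ccs[i]
                else NA_real_,
        rel_area_a = if (i <= nrow(pa)) ra[i] else NA_real_,
        ccs_b = if (i <= nrow(pb) && !is.null(pb$ccs)) pb$ccs[i]
                else NA_real_,
        rel_area_b = if (i <= nrow(pb)) rb[i] else NA_real_,
        missing = i > n, inversion = inv)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a profile from CSV
#'
#' Columns: `sample`, `mz`, `ccs`, `area`, `structure`, `core`, plus
#' optional `composition` and feature flag columns.
#'
#' @param path CSV path.
#' @return A `glyco_profile` (single-sample file) or list of profiles.
#' @export
read_profile_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("sample", "mz", "area", "core") %in% names(d))) {
    stop("profile CSV needs columns sample, mz, area, core")
  }
  samples <- unique(d$sample)
  out <- lapply(samples, function(s) {
    glyco_profile(s, d[d$sample == s, setdiff(names(d), "sample"),
                       drop = FALSE])
  })
  if (length(out) == 1) out[[1]] else stats::setNames(out, samples)
}

#' Write a profile to CSV
#' @param p A `glyco_profile`.
#' @param path Output path.
#' @export
write_profile_csv <- function(p, path) {
  d <- cbind(sample = p$sample, p$peaks)
  utils::write.csv(d, path, row.names = FALSE)
}
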