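# CCS reference-library reading/writing and (m/z, CCS) matching.
#
# A library record couples a composition (and optionally a full structure)
# with its theoretical m/z and the CCS values measured on one or both
# instrument families.  Because CCS is an instrument-independent molecular
# property, such libraries support database-driven assignment: an observed
# (m/z, CCS) pair is matched against records within joint tolerances.

.lib_columns <- c("composition", "structure", "z", "mz", "ccs_tims",
                  "ccs_twims", "source", "accession")

#' Read a CCS reference library
#'
#' CSV dialect: fixed columns `composition`, `structure`, `z`, `mz`,
#' `ccs_tims`, `ccs_twims`, `source`, `accession` (extra columns are
#' tolerated and preserved).  JSON dialect: an array of objects with the
#' same fields.  Each record must carry at least one CCS value and an m/z
#' consistent with its composition within `check_ppm`.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"json"` (default: by file extension).
#' @param check_ppm Tolerance for the m/z-vs-composition consistency
#'   check.
#' @return data.frame of validated records (class `ccs_library`), with
#'   attribute `rejected`: a data.frame of refused rows and reasons.
#' @export
read_library <- function(path, dialect = NULL, check_ppm = 5) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
               else "csv"
  }
  dialect <- match.arg(dialect, c("csv", "json"))
  d <- if (dialect == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path))
  }
  if (nrow(d) == 0) stop("library file contains no records: ", path)
  required <- c("composition", "z", "mz")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stop("library is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(.lib_columns, names(d))) d[[col]] <- NA
  reasons <- character(nrow(d))
  for (i in seq_len(nrow(d))) {
    has_ccs <- (!is.na(d$ccs_tims[i]) && d$ccs_tims[i] > 0) ||
      (!is.na(d$ccs_twims[i]) && d$ccs_twims[i] > 0)
    if (!has_ccs) { reasons[i] <- "no CCS value"; next }
    comp <- tryCatch(parse_composition(d$composition[i]),
                     error = function(e) NULL)
    if (is.null(comp)) { reasons[i] <- "unparseable composition"; next }
    mz_theo <- glycan_mz(comp, d$z[i])
    ppm <- abs(d$mz[i] - mz_theo) / mz_theo * 1e6
    if (ppm > check_ppm) {
      reasons[i] <- sprintf("m/z inconsistent with composition (%.1f ppm)",
                            ppm)
    }
  }
  ok <- reasons == ""
  out <- d[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- data.frame(row = which(!ok),
                                      reason = reasons[!ok])
  class(out) <- c("ccs_library", "data.frame")
  out
}

#' Write a CCS reference library
#'
#' @param lib A `ccs_library` or compatible data.frame.
#' @param path Output path.
#' @param dialect `"csv"` or `"json"` (default: by extension).
#' @export
write_library <- function(lib, path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
               else "csv"
  }
  dialect <- match.arg(dialect, c("csv", "json"))
  d <- as.data.frame(lib)
  cols <- c(intersect(.lib_columns, names(d)),
            setdiff(names(d), .lib_columns))
  d <- d[cols]
  if (dialect == "csv") {
    utils::write.csv(d, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(d, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Match an observed (m/z, CCS) pair against a reference library
#'
#' Candidates must agree in charge, lie within `mz_tol_ppm` of the record
#' m/z and within `ccs_tol_pct` percent of the record CCS.  Candidates are
#' ranked by the combined normalised distance
#' d = sqrt((dppm / mz_tol)^2 + (dCCS% / ccs_tol)^2).
#'
#' The default CCS tolerance of 0.5 % is half the observed upper bound
#' (< 1 %) on the TIMS-vs-TWIMS standard deviation of glycan CCS values.
#'
#' @param query_mz,query_ccs Observed m/z and CCS.
#' @param z Charge state of the query.
#' @param records A `ccs_library`.
#' @param mz_tol_ppm m/z tolerance (ppm).
#' @param ccs_tol_pct CCS tolerance (percent).
#' @param instrument `"tims"`, `"twims"`, or `"any"`: which library CCS
#'   column is compared (with `"any"`, TIMS is preferred, TWIMS used when
#'   TIMS is absent).
#' @return The matching records with columns `ppm`, `dccs_pct` and
#'   `distance` appended, sorted by distance (zero rows when nothing
#'   matches).
#' @export
match_library <- function(query_mz, query_ccs, z, records,
                          mz_tol_ppm = 10, ccs_tol_pct = 0.5,
                          instrument = c("any", "tims", "twims")) {
  stopifnot(mz_tol_ppm > 0, ccs_tol_pct > 0)
  instrument <- match.arg(instrument)
  d <- as.data.frame(records)
  ccs_ref <- switch(instrument,
    tims = d$ccs_tims,
    twims = d$ccs_twims,
    any = ifelse(!is.na(d$ccs_tims), d$ccs_tims, d$ccs_twims)
  )
  ppm <- (query_mz - d$mz) / d$mz * 1e6
  dccs <- (query_ccs - ccs_ref) / ccs_ref * 100
  ok <- !is.na(ccs_ref) & d$z == z & abs(ppm) <= mz_tol_ppm &
    abs(dccs) <= ccs_tol_pct
  out <- d[ok, , drop = FALSE]
  out$ppm <- ppm[ok]
  out$dccs_pct <- dccs[ok]
  out$distance <- sqrt((out$ppm / mz_tol_ppm)^2 +
                         (out$dccs_pct / ccs_tol_pct)^2)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Path of the packaged synthetic demo library
#'
#' A 49-record stand-in for a processed porcine-gastric-mucin O-glycan
#' CCS library (composition, structure where known, m/z, TIMS and TWIMS
#' CCS).  The records are synthetic: compositions and structures are
#' typical PGM O-glycans with plausible CCS values, constructed for
#' examples and tests; they are not measured data.
#'
#' @return File path of the CSV inside the installed package.
#' @export
demo_library_path <- function() {
  system.file("extdata", "pgm_demo_library_synthetic.csv",
              package = "glycomob", mustWork = TRUE)
}
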