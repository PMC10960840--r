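# Monoisotopic mass arithmetic for mucin-type O-glycan alditols.
#
# All masses are monoisotopic and derived from CODATA/IUPAC atomic masses
# (>= 6 decimal places).  Negative-mode deprotonation uses the 1.007276 Da
# proton convention, i.e. the electron mass is folded into the proton mass.

.atomic <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

.formula_mass <- function(counts) {
  sum(.atomic[names(counts)] * counts)
}

#' Physical mass constants used throughout the package
#'
#' @return Named numeric vector (Da) with elements `water` (H2O),
#'   `reduction_2H` (the 2H added by borohydride reduction of the former
#'   reducing end), `proton` (1.007276, electron folded in), and `sulfate`
#'   (SO3, the mass added per sulfate modification).
#' @export
#' @examples
#' mass_constants()["water"]
mass_constants <- function() {
  c(
    water        = .formula_mass(c(H = 2, O = 1)),
    reduction_2H = .formula_mass(c(H = 2)),
    proton       = 1.007276,
    sulfate      = .formula_mass(c(S = 1, O = 3))
  )
}

# residue (dehydrated monomer) elemental formulas
.residue_formulas <- list(
  Hex    = c(C = 6,  H = 10, O = 5),
  HexNAc = c(C = 8,  H = 13, N = 1, O = 5),
  dHex   = c(C = 6,  H = 10, O = 4),
  NeuAc  = c(C = 11, H = 17, N = 1, O = 8)
)

#' Monosaccharide residue classes handled by the mass module
#' @return Character vector of class names in canonical order.
#' @export
monosaccharide_classes <- function() names(.residue_formulas)

#' Monoisotopic residue mass of a monosaccharide class
#'
#' Residue means the dehydrated monomer as it occurs inside a glycan chain
#' (e.g. Hex = C6H10O5, 162.052824 Da).
#'
#' @param cls Character: one of `"Hex"`, `"HexNAc"`, `"dHex"`, `"NeuAc"`.
#' @return Mass in Da.
#' @export
#' @examples
#' residue_mass("Hex")
residue_mass <- function(cls) {
  if (length(cls) != 1L || !cls %in% names(.residue_formulas)) {
    stop("unknown monosaccharide class: ", paste(cls, collapse = ", "))
  }
  .formula_mass(.residue_formulas[[cls]])
}

.residue_masses <- function() {
  vapply(names(.residue_formulas),
         function(n) .formula_mass(.residue_formulas[[n]]), numeric(1))
}

#' Construct a glycan composition
#'
#' A composition is a multiset of monosaccharide classes plus a sulfate
#' count and a reduced-end (alditol) flag.  Reductive beta-elimination
#' releases mucin-type O-glycans as alditols, so `reduced = TRUE` is the
#' default.
#'
#' @param Hex,HexNAc,dHex,NeuAc Non-negative integer residue counts.
#' @param S Non-negative integer sulfate count (modelled as +SO3, not as a
#'   residue).
#' @param reduced Logical: alditol (open-chain reduced end)?
#' @return An object of class `glycomp`.
#' @export
#' @examples
#' glycomp(Hex = 2, HexNAc = 2, dHex = 1)
glycomp <- function(Hex = 0, HexNAc = 0, dHex = 0, NeuAc = 0, S = 0,
                    reduced = TRUE) {
  counts <- c(Hex = Hex, HexNAc = HexNAc, dHex = dHex, NeuAc = NeuAc)
  if (any(counts < 0) || S < 0 || any(counts != round(counts)) ||
      S != round(S)) {
    stop("composition counts must be non-negative integers")
  }
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(
    list(counts = counts, sulfate = as.integer(S), reduced = isTRUE(reduced)),
    class = "glycomp"
  )
}

#' @export
format.glycomp <- function(x, ...) {
  parts <- character(0)
  for (cls in names(x$counts)) {
    if (x$counts[[cls]] > 0) parts <- c(parts, paste0(cls, x$counts[[cls]]))
  }
  if (x$sulfate > 0) parts <- c(parts, paste0("S", x$sulfate))
  out <- paste(parts, collapse = "")
  if (out == "") out <- "(empty)"
  if (x$reduced) out <- paste0(out, "-ol")
  out
}

#' @export
print.glycomp <- function(x, ...) {
  cat("<glycomp> ", format(x), "  neutral mass ",
      if (sum(x$counts) + x$sulfate > 0)
        sprintf("%.6f Da", neutral_mass(x)) else "(undefined)",
      "\n", sep = "")
  invisible(x)
}

#' Parse a canonical composition string
#'
#' Accepts the fixed-order canonical form produced by
#' [format.glycomp()], e.g. `"Hex2HexNAc2dHex1S1"`, with an optional
#' trailing `"-ol"` marking the alditol.
#'
#' @param text Composition string.
#' @param reduced Default reduced flag when no `-ol` suffix is present.
#' @return A `glycomp` object.
#' @export
parse_composition <- function(text, reduced = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  if (grepl("-ol$", s)) {
    reduced <- TRUE
    s <- sub("-ol$", "", s)
  }
  counts <- c(Hex = 0L, HexNAc = 0L, dHex = 0L, NeuAc = 0L, S = 0L)
  pat <- "(HexNAc|dHex|NeuAc|Hex|S)(\\d+)"
  rest <- s
  while (nchar(rest) > 0) {
    m <- regexpr(paste0("^", pat), rest)
    if (m == -1) stop("malformed composition string: ", text)
    tok <- regmatches(rest, m)
    cls <- sub(pat, "\\1", tok)
    n <- as.integer(sub(pat, "\\2", tok))
    counts[[cls]] <- counts[[cls]] + n
    rest <- substring(rest, attr(m, "match.length") + 1L)
  }
  glycomp(Hex = counts[["Hex"]], HexNAc = counts[["HexNAc"]],
          dHex = counts[["dHex"]], NeuAc = counts[["NeuAc"]],
          S = counts[["S"]], reduced = reduced)
}

#' Neutral monoisotopic mass of a composition
#'
#' Sum of residue masses plus one water (chain termini) plus, for alditols,
#' the 2H of reduction, plus SO3 per sulfate.
#'
#' @param comp A `glycomp` object with at least one residue or sulfate.
#' @return Mass in Da.
#' @export
#' @examples
#' neutral_mass(glycomp(Hex = 1))            # reduced hexose
#' neutral_mass(glycomp(Hex = 1, reduced = FALSE))  # free hexose
neutral_mass <- function(comp) {
  stopifnot(inherits(comp, "glycomp"))
  if (sum(comp$counts) < 1L) {
    stop("empty composition has no defined mass")
  }
  k <- mass_constants()
  sum(.residue_masses() * comp$counts) +
    comp$sulfate * k[["sulfate"]] +
    k[["water"]] +
    if (comp$reduced) k[["reduction_2H"]] else 0
}

#' m/z of a deprotonated glycan ion
#'
#' Negative-mode electrospray of released O-glycans yields \[M - zH\]^z-
#' ions; this computes (M - z * 1.007276) / z.
#'
#' @param comp A `glycomp` object.
#' @param z Positive integer charge (number of removed protons).
#' @return m/z value.
#' @export
#' @examples
#' glycan_mz(glycomp(Hex = 2, HexNAc = 2, dHex = 1), z = 1)  # ~895.34
glycan_mz <- function(comp, z = 1L) {
  if (!is.numeric(z) || length(z) != 1L || z < 1 || z != round(z)) {
    stop("charge z must be a positive integer")
  }
  (neutral_mass(comp) - z * mass_constants()[["proton"]]) / z
}

#' Charge states expected for a glycan of given neutral mass
#'
#' Doubly deprotonated species are only observed above a mass threshold
#' (default 1200 Da); smaller glycans appear singly charged only.
#'
#' @param neutral Neutral mass in Da (> 0).
#' @param threshold Mass above which z = 2 is also expected (Da).
#' @return Integer vector of charge states.
#' @export
allowed_charges <- function(neutral, threshold = 1200) {
  stopifnot(is.numeric(neutral), neutral > 0)
  if (neutral <= threshold) 1L else c(1L, 2L)
}

#' Default residue-count bounds for composition search
#'
#' Covers the observed mass range (up to about 2500 Da) of mucin O-glycan
#' alditols.
#' @return Named integer vector of per-class maxima.
#' @export
default_comp_bounds <- function() {
  c(Hex = 8L, HexNAc = 8L, dHex = 4L, NeuAc = 4L, S = 2L)
}

#' Search glycan compositions matching an observed m/z
#'
#' Exhaustively enumerates reduced compositions within per-class count
#' bounds and returns those whose deprotonated m/z lies within a ppm
#' tolerance of the observation, subject to biosynthetic constraints
#' (mucin-type alditols contain at least one HexNAc, the protein-linked
#' GalNAc).
#'
#' @param observed_mz Observed m/z.
#' @param z Charge (positive integer).
#' @param tol_ppm Tolerance in ppm (> 0).
#' @param bounds Named integer vector of per-class maxima
#'   (`Hex`, `HexNAc`, `dHex`, `NeuAc`, `S`), see [default_comp_bounds()].
#' @param min_hexnac Minimum HexNAc count (default 1).
#' @param reduced Search reduced (alditol) compositions?
#' @return A data.frame with columns `composition` (canonical string),
#'   `Hex`, `HexNAc`, `dHex`, `NeuAc`, `S`, `neutral`, `mz`, `ppm`, sorted
#'   by absolute ppm error; zero rows when nothing matches.
#' @export
#' @examples
#' search_compositions(675.246, z = 1, tol_ppm = 10)
search_compositions <- function(observed_mz, z = 1L, tol_ppm = 10,
                                bounds = default_comp_bounds(),
                                min_hexnac = 1L, reduced = TRUE) {
  stopifnot(tol_ppm > 0)
  need <- c("Hex", "HexNAc", "dHex", "NeuAc", "S")
  if (length(bounds) == 0 || !all(need %in% names(bounds))) {
    stop("bounds must name all of: ", paste(need, collapse = ", "))
  }
  if (any(bounds < 0) || !any(bounds[setdiff(need, "S")] > 0)) {
    stop("bounds admit no composition")
  }
  k <- mass_constants()
  rm <- .residue_masses()
  target_neutral <- observed_mz * z + z * k[["proton"]]
  base <- k[["water"]] + if (reduced) k[["reduction_2H"]] else 0

  grid <- expand.grid(
    Hex = 0:bounds[["Hex"]], HexNAc = min_hexnac:bounds[["HexNAc"]],
    dHex = 0:bounds[["dHex"]], NeuAc = 0:bounds[["NeuAc"]],
    S = 0:bounds[["S"]], KEEP.OUT.ATTRS = FALSE
  )
  neutral <- base +
    grid$Hex * rm[["Hex"]] + grid$HexNAc * rm[["HexNAc"]] +
    grid$dHex * rm[["dHex"]] + grid$NeuAc * rm[["NeuAc"]] +
    grid$S * k[["sulfate"]]
  mz <- (neutral - z * k[["proton"]]) / z
  ppm <- (mz - observed_mz) / observed_mz * 1e6
  hit <- abs(ppm) <= tol_ppm & (grid$Hex + grid$HexNAc +
                                  grid$dHex + grid$NeuAc) >= 1
  out <- grid[hit, , drop = FALSE]
  out$neutral <- neutral[hit]
  out$mz <- mz[hit]
  out$ppm <- ppm[hit]
  out <- out[order(abs(out$ppm)), , drop = FALSE]
  comp_str <- vapply(seq_len(nrow(out)), function(i) {
    format(glycomp(Hex = out$Hex[i], HexNAc = out$HexNAc[i],
                   dHex = out$dHex[i], NeuAc = out$NeuAc[i],
                   S = out$S[i], reduced = reduced))
  }, character(1))
  out <- cbind(composition = comp_str, out)
  rownames(out) <- NULL
  out
}
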