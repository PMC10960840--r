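# Negative-mode fragment generation and diagnostic scoring for glycan
# alditols.
#
# Collision-induced dissociation of deprotonated glycans follows the
# Domon/Costello nomenclature: B/C ions retain the non-reducing end, Y/Z
# the reducing (alditol) end, and A-type cross-ring cleavages carry the
# linkage-position information that makes negative-mode CID diagnostic of
# the O-glycan core.  Mass bookkeeping for a single glycosidic cleavage:
#   neutral(B) = sum of residues on the non-reducing side
#   neutral(C) = neutral(B) + H2O
#   neutral(Y) = sum of reducing-side residues + H2O (+ 2H if alditol)
#   neutral(Z) = neutral(Y) - H2O
# so B + Y and C + Z both reconstruct the intact neutral mass exactly.

.subtree_residue_mass <- function(node) {
  m <- residue_mass(.residue_identities[[node$identity]])
  for (k in node$children) m <- m + .subtree_residue_mass(k)
  m
}

.subtree_size <- function(node) {
  1L + sum(vapply(node$children, .subtree_size, integer(1)))
}

#' Default cross-ring (A-ion) mass offsets
#'
#' Offsets in Da applied to the C-ion neutral mass of the bond above the
#' cleaved residue.  The classic negative-mode diagnostics are the 0,2A
#' (loss of C4H8O4, -120.042 Da from the C equivalent) and 2,4A (loss of
#' C4H8O4 + C2H4O2, -180.063 Da) cleavages of hexose and HexNAc rings;
#' values are computed from elemental formulas and can be replaced via the
#' `a_offsets` argument of [generate_fragments()].
#'
#' @return data.frame with columns `class`, `label`, `offset`.
#' @export
default_a_offsets <- function() {
  c2h4o2 <- .formula_mass(c(C = 2, H = 4, O = 2))
  c4h8o4 <- .formula_mass(c(C = 4, H = 8, O = 4))
  data.frame(
    class = c("Hex", "Hex", "HexNAc", "HexNAc", "dHex", "dHex"),
    label = rep(c("0,2A", "2,4A"), 3),
    offset = rep(c(-c4h8o4, -(c4h8o4 + c2h4o2)), 3),
    stringsAsFactors = FALSE
  )
}

.proton <- function() mass_constants()[["proton"]]

.frag_row <- function(kind, site, neutral, retains_alditol) {
  data.frame(kind = kind, site = site, neutral = neutral,
             mz = neutral - .proton(), retains_alditol = retains_alditol,
             stringsAsFactors = FALSE)
}

# enumerate edges with the residue path name for the site label and the
# ids of the ancestor edges (root side), so nesting of two cleavage sites
# can be decided without comparing node contents
.edges_with_sites <- function(node, ancestors = integer(0),
                              env = new.env(parent = emptyenv())) {
  if (is.null(env$edges)) { env$edges <- list(); env$id <- 0L }
  for (i in seq_along(node$children)) {
    k <- node$children[[i]]
    site <- paste0(k$identity, "(", k$anomer,
                   ifelse(is.na(k$carbon), "?", k$carbon), "-",
                   ifelse(is.na(k$pos), "?", k$pos), ")", ">",
                   node$identity)
    env$id <- env$id + 1L
    id <- env$id
    env$edges[[id]] <- list(parent = node, child = k, site = site,
                            id = id, ancestors = ancestors)
    .edges_with_sites(k, c(ancestors, id), env)
  }
  env$edges
}

#' Generate theoretical negative-mode fragments of a glycan structure
#'
#' Produces singly deprotonated B/C/Y/Z glycosidic fragments, A-type
#' cross-ring fragments (via a configurable offset table relative to the
#' C ion), and, with `max_cleavages = 2`, internal double-cleavage
#' fragments (labelled e.g. `"Y/Y"`, `"B/Y"`).  Fragments are deduplicated
#' by (kind, neutral mass).
#'
#' @param s A `glycan_structure`.
#' @param kinds Subset of `c("B","C","Y","Z","A")`.
#' @param max_cleavages 1 or 2.
#' @param a_offsets Cross-ring offset table, see [default_a_offsets()].
#' @return data.frame with columns `kind`, `site`, `neutral`, `mz`
#'   (singly deprotonated) and `retains_alditol`.
#' @export
#' @examples
#' s <- parse_structure("Fuc(a1-2)Gal(b1-3)[Gal(b1-4)GlcNAc(b1-6)]GalNAc-ol")
#' head(generate_fragments(s))
generate_fragments <- function(s, kinds = c("B", "C", "Y", "Z", "A"),
                               max_cleavages = 1L,
                               a_offsets = default_a_offsets()) {
  stopifnot(inherits(s, "glycan_structure"))
  if (!max_cleavages %in% c(1L, 2L)) stop("max_cleavages must be 1 or 2")
  kinds <- match.arg(kinds, c("B", "C", "Y", "Z", "A"), several.ok = TRUE)
  k <- mass_constants()
  water <- k[["water"]]
  red <- if (s$reduced) k[["reduction_2H"]] else 0
  parent_neutral <- if (.subtree_size(s$root) >= 1)
    .subtree_residue_mass(s$root) + water + red else NA_real_

  edges <- .edges_with_sites(s$root)
  rows <- list()
  for (e in edges) {
    sub <- .subtree_residue_mass(e$child)
    b <- sub
    y <- parent_neutral - sub
    if ("B" %in% kinds) rows <- c(rows, list(.frag_row("B", e$site, b, FALSE)))
    if ("C" %in% kinds) rows <- c(rows, list(.frag_row("C", e$site, b + water, FALSE)))
    if ("Y" %in% kinds) rows <- c(rows, list(.frag_row("Y", e$site, y, s$reduced)))
    if ("Z" %in% kinds) rows <- c(rows, list(.frag_row("Z", e$site, y - water, s$reduced)))
    if ("A" %in% kinds) {
      cls <- .residue_identities[[e$parent$identity]]
      offs <- a_offsets[a_offsets$class == cls, , drop = FALSE]
      # cross-ring cleavage of the residue below this bond: the C-ion
      # equivalent is the full subtree hanging from the parent residue
      c_equiv <- .subtree_residue_mass(e$parent) + water
      for (j in seq_len(nrow(offs))) {
        rows <- c(rows, list(.frag_row(
          paste0(offs$label[j]),
          paste0(offs$label[j], "@", e$parent$identity),
          c_equiv + offs$offset[j], FALSE
        )))
      }
    }
  }

  if (max_cleavages == 2L && length(edges) >= 2) {
    glyco <- intersect(kinds, c("B", "C", "Y", "Z"))
    for (i in seq_along(edges)) {
      for (j in seq_along(edges)) {
        if (i >= j) next
        a <- edges[[i]]; b <- edges[[j]]
        sa <- .subtree_residue_mass(a$child)
        sb <- .subtree_residue_mass(b$child)
        nested_ab <- a$id %in% b$ancestors  # b lies inside a's subtree
        nested_ba <- b$id %in% a$ancestors
        site <- paste(a$site, b$site, sep = " & ")
        if (!nested_ab && !nested_ba) {
          # both subtrees removed from the root-retaining fragment
          for (k1 in intersect(glyco, c("Y", "Z"))) {
            for (k2 in intersect(glyco, c("Y", "Z"))) {
              if (k1 > k2) next
              n <- parent_neutral - sa - sb -
                water * ((k1 == "Z") + (k2 == "Z"))
              rows <- c(rows, list(.frag_row(paste0(k1, "/", k2), site, n,
                                             s$reduced)))
            }
          }
        } else {
          # nested: outer B/C retained, inner subtree lost as Y/Z cut
          outer <- if (nested_ab) a else b
          inner <- if (nested_ab) b else a
          so <- .subtree_residue_mass(outer$child)
          si <- .subtree_residue_mass(inner$child)
          for (k1 in intersect(glyco, c("B", "C"))) {
            for (k2 in intersect(glyco, c("Y", "Z"))) {
              n <- so - si + water * (k1 == "C") - water * (k2 == "Z")
              rows <- c(rows, list(.frag_row(paste0(k1, "/", k2), site, n,
                                             FALSE)))
            }
          }
        }
      }
    }
  }

  if (length(rows) == 0) {
    return(.frag_row(character(0), character(0), numeric(0), logical(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[out$neutral > 0, , drop = FALSE]
  out <- out[!duplicated(paste(out$kind, round(out$neutral, 6))), ,
             drop = FALSE]
  out <- out[order(out$neutral, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.kind_rank <- function(kind) {
  base <- c(B = 1, C = 2, Y = 3, Z = 4)
  r <- base[substr(kind, 1, 1)]
  r[is.na(r)] <- 5  # A-type and internals rank after single glycosidic
  r
}

#' Annotate an MS/MS peak list with candidate fragments
#'
#' Each peak is matched to the nearest candidate fragment within a ppm
#' tolerance; unmatched peaks are dropped.  Ties in mass are broken by
#' fragment kind order B < C < Y < Z < A.
#'
#' @param peaks data.frame or matrix with columns `mz` and `intensity`
#'   (or a two-column numeric object in that order).
#' @param candidates Fragment table from [generate_fragments()].
#' @param tol_ppm Matching tolerance in ppm (> 0).
#' @return data.frame with columns `peak_mz`, `intensity`, `kind`, `site`,
#'   `frag_mz`, `ppm`; zero rows when nothing matches.
#' @export
annotate_spectrum <- function(peaks, candidates, tol_ppm = 20) {
  stopifnot(tol_ppm > 0)
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) == 0) {
    return(data.frame(peak_mz = numeric(0), intensity = numeric(0),
                      kind = character(0), site = character(0),
                      frag_mz = numeric(0), ppm = numeric(0)))
  }
  if (!all(c("mz", "intensity") %in% names(peaks))) {
    names(peaks)[1:2] <- c("mz", "intensity")
  }
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    mz <- peaks$mz[i]
    ppm <- (mz - candidates$mz) / candidates$mz * 1e6
    ok <- which(abs(ppm) <= tol_ppm)
    if (length(ok) == 0) return(NULL)
    best <- ok[order(abs(ppm[ok]), .kind_rank(candidates$kind[ok]))][1]
    data.frame(peak_mz = mz, intensity = peaks$intensity[i],
               kind = candidates$kind[best], site = candidates$site[best],
               frag_mz = candidates$mz[best], ppm = ppm[best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(peak_mz = numeric(0), intensity = numeric(0),
                      kind = character(0), site = character(0),
                      frag_mz = numeric(0), ppm = numeric(0)))
  }
  rownames(out) <- NULL
  out
}

#' Derive diagnostic fragment rules from candidate structures
#'
#' For each candidate structure, the fragment masses absent from every
#' candidate carrying a *different* label become the required set of a
#' rule implying the structure's core (or, with `imply = "structure"`,
#' its serialised text).  Discrimination is against competing labels, not
#' against isomers of the same core, mirroring manual negative-mode
#' assignment practice: a label is called when its discriminating
#' fragments are all observed.  Structures whose fragment set is entirely
#' shared with a competing label get an empty required set and can never
#' fire (glycosidic masses alone cannot separate pure linkage isomers).
#'
#' @param structures List of `glycan_structure` objects (default: the
#'   bare core 1-4 templates).
#' @param imply `"core"` or `"structure"` - what a satisfied rule implies.
#' @param kinds,max_cleavages Passed to [generate_fragments()].
#' @param digits Rounding used when comparing fragment masses for
#'   uniqueness.
#' @return List of rules, each a list with `name`, `required` (numeric
#'   fragment m/z values), `forbidden` (numeric), `implies`, `weight`.
#' @export
derive_diagnostic_rules <- function(structures = core_templates(),
                                    imply = c("core", "structure"),
                                    kinds = c("B", "C", "Y", "Z", "A"),
                                    max_cleavages = 1L, digits = 3) {
  imply <- match.arg(imply)
  frags <- lapply(structures, generate_fragments, kinds = kinds,
                  max_cleavages = max_cleavages)
  keys <- lapply(frags, function(f) unique(round(f$mz, digits)))
  labs <- vapply(structures, function(s) {
    if (imply == "core") classify_core(s) else serialize_structure(s)
  }, character(1))
  rules <- vector("list", length(structures))
  for (i in seq_along(structures)) {
    others <- unique(unlist(keys[labs != labs[i]]))
    uniq <- setdiff(keys[[i]], others)
    lab <- labs[i]
    rules[[i]] <- list(
      name = paste0("unique_fragments_", i, "_", lab),
      required = uniq,
      forbidden = numeric(0),
      implies = lab,
      weight = 1
    )
  }
  rules
}

#' Bare core template structures 1-4
#'
#' @return Named list of `glycan_structure` objects for the four common
#'   mucin O-glycan cores.
#' @export
core_templates <- function() {
  list(
    core1 = parse_structure("Gal(b1-3)GalNAc-ol"),
    core2 = parse_structure("Gal(b1-3)[GlcNAc(b1-6)]GalNAc-ol"),
    core3 = parse_structure("GlcNAc(b1-3)GalNAc-ol"),
    core4 = parse_structure("GlcNAc(b1-3)[GlcNAc(b1-6)]GalNAc-ol")
  )
}

#' Score core/structure labels from annotated fragments
#'
#' A rule is satisfied when every required fragment m/z is matched by some
#' annotated peak (within `digits` rounding) and no forbidden fragment is
#' present; rules with empty required sets never fire.  The score of a
#' label is the summed weight of its satisfied rules minus the summed
#' weight of rules whose forbidden set is violated.
#'
#' @param matches Annotation table from [annotate_spectrum()].
#' @param rules Rule list, see [derive_diagnostic_rules()].
#' @param digits Rounding for m/z comparison.
#' @return data.frame of `label`, `score` sorted by decreasing score, with
#'   attributes `assigned` (logical: any positive score) and `tie`
#'   (logical: top score shared).
#' @export
score_core_diagnostics <- function(matches, rules, digits = 3) {
  if (length(rules) == 0) stop("rule set is empty")
  observed <- unique(round(matches$peak_mz, digits))
  labels <- unique(vapply(rules, `[[`, character(1), "implies"))
  score <- stats::setNames(numeric(length(labels)), labels)
  for (r in rules) {
    req <- round(r$required, digits)
    forb <- round(r$forbidden, digits)
    if (length(req) > 0 && all(req %in% observed)) {
      score[r$implies] <- score[r$implies] + r$weight
    }
    if (length(forb) > 0 && any(forb %in% observed)) {
      score[r$implies] <- score[r$implies] - r$weight
    }
  }
  out <- data.frame(label = names(score), score = as.numeric(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "assigned") <- any(out$score > 0)
  attr(out, "tie") <- nrow(out) > 1 && out$score[1] == out$score[2]
  out
}
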