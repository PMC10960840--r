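# Tree model of O-glycan alditol structures.
#
# Structures are written in a condensed IUPAC-like text form, e.g.
#   "Fuc(a1-2)Gal(b1-3)[GlcNAc(b1-6)]GalNAc-ol"
# Reading left to right, each residue is attached to the residue that
# follows it; square brackets enclose branches attached to the residue
# after the closing bracket.  The rightmost residue is the root; for
# reduced structures it carries the "-ol" suffix (GalNAc-ol for mucin-type
# glycans).  Unknown anomers/positions are written "?".

.residue_identities <- c(
  Gal = "Hex", Glc = "Hex", Man = "Hex",
  GalNAc = "HexNAc", GlcNAc = "HexNAc",
  Fuc = "dHex",
  Neu5Ac = "NeuAc", NeuAc = "NeuAc"
)

.new_residue <- function(identity, anomer = "?", carbon = NULL,
                         pos = NA_integer_, children = list()) {
  if (!identity %in% names(.residue_identities)) {
    stop("unknown residue identity: ", identity)
  }
  if (is.null(carbon)) {
    # sialic acids link through their anomeric C2, aldoses through C1
    carbon <- if (.residue_identities[[identity]] == "NeuAc") 2L else 1L
  }
  list(identity = identity, anomer = anomer, carbon = carbon, pos = pos,
       children = children)
}

.residue_token <- "([A-Za-z0-9]+)\\((a|b|\\?)([12?])-([0-9?])\\)"

# split "prefix" (everything left of a residue) into children of `parent`,
# consuming from the right end
.parse_prefix <- function(prefix, parent, full) {
  while (nchar(prefix) > 0) {
    if (grepl("\\]$", prefix)) {
      # bracketed branch: find matching "[" scanning right to left
      chars <- strsplit(prefix, "")[[1]]
      depth <- 0L
      open <- NA_integer_
      for (i in rev(seq_along(chars))) {
        if (chars[i] == "]") depth <- depth + 1L
        if (chars[i] == "[") {
          depth <- depth - 1L
          if (depth == 0L) { open <- i; break }
        }
      }
      if (is.na(open)) {
        stop("parse error: unbalanced ']' near position ",
             nchar(full), " in \"", full, "\"")
      }
      inner <- substr(prefix, open + 1L, nchar(prefix) - 1L)
      parent$children <- c(parent$children,
                           list(.parse_linked_chain(inner, full)))
      prefix <- substr(prefix, 1L, open - 1L)
    } else {
      m <- regexpr(paste0(.residue_token, "$"), prefix)
      if (m == -1) {
        stop("parse error near position ", nchar(prefix),
             " in \"", full, "\"")
      }
      tok <- regmatches(prefix, m)
      node <- .token_to_residue(tok)
      rest <- substr(prefix, 1L, nchar(prefix) - attr(m, "match.length"))
      node <- .parse_prefix(rest, node, full)
      parent$children <- c(parent$children, list(node))
      prefix <- ""
    }
  }
  parent$children <- .order_children(parent$children)
  parent
}

.token_to_residue <- function(tok) {
  name <- sub(.residue_token, "\\1", tok)
  ano <- sub(.residue_token, "\\2", tok)
  carbon <- sub(.residue_token, "\\3", tok)
  pos <- sub(.residue_token, "\\4", tok)
  .new_residue(name, anomer = ano,
               carbon = if (carbon == "?") NA_integer_
                        else as.integer(carbon),
               pos = if (pos == "?") NA_integer_ else as.integer(pos))
}

# a chain whose rightmost residue carries a linkage (bracket content)
.parse_linked_chain <- function(s, full) {
  m <- regexpr(paste0(.residue_token, "$"), s)
  if (m == -1) stop("parse error inside branch \"", s, "\" of \"", full, "\"")
  node <- .token_to_residue(regmatches(s, m))
  rest <- substr(s, 1L, nchar(s) - attr(m, "match.length"))
  .parse_prefix(rest, node, full)
}

.order_children <- function(children) {
  if (length(children) < 2L) return(children)
  pos <- vapply(children, function(c) {
    if (is.na(c$pos)) 99L else c$pos
  }, integer(1))
  if (anyDuplicated(pos[!is.na(pos) & pos != 99L])) {
    stop("duplicate linkage positions on one parent")
  }
  children[order(pos)]
}

#' Parse a condensed O-glycan structure string
#'
#' @param text Structure in condensed form, e.g.
#'   `"Gal(b1-3)[GlcNAc(b1-6)]GalNAc-ol"`.  Residue names: Gal, Glc, Man,
#'   GalNAc, GlcNAc, Fuc, Neu5Ac.  Anomer `a`/`b`/`?`, linkage position a
#'   digit or `?`.  A trailing `-ol` marks the reduced (alditol) root.
#' @return An object of class `glycan_structure` with elements `root`
#'   (nested residue list), `reduced` (logical) and `text` (canonical
#'   serialisation; branches ordered by linkage position).
#' @export
#' @examples
#' parse_structure("Fuc(a1-2)Gal(b1-3)[GlcNAc(b1-6)]GalNAc-ol")
parse_structure <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("\\s", "", text)
  reduced <- grepl("-ol$", s)
  if (reduced) s <- sub("-ol$", "", s)
  m <- regexpr("([A-Za-z0-9]+)$", s)
  if (m == -1 || attr(m, "match.length") == 0L) {
    stop("parse error: no root residue at end of \"", text, "\"")
  }
  root_name <- regmatches(s, m)
  if (!root_name %in% names(.residue_identities)) {
    stop("parse error: invalid root residue \"", root_name,
         "\" at position ", nchar(s), " in \"", text, "\"")
  }
  root <- .new_residue(root_name)
  prefix <- substr(s, 1L, nchar(s) - attr(m, "match.length"))
  root <- .parse_prefix(prefix, root, text)
  out <- structure(list(root = root, reduced = reduced, text = NA_character_),
                   class = "glycan_structure")
  out$text <- serialize_structure(out)
  out
}

.serialize_residue <- function(node, is_root, reduced) {
  kids <- node$children
  pre <- ""
  if (length(kids) > 0) {
    main <- .serialize_residue(kids[[1]], FALSE, FALSE)
    branches <- vapply(kids[-1], function(k) {
      paste0("[", .serialize_residue(k, FALSE, FALSE), "]")
    }, character(1))
    pre <- paste0(main, paste(branches, collapse = ""))
  }
  self <- node$identity
  if (!is_root) {
    p <- if (is.na(node$pos)) "?" else node$pos
    cb <- if (is.na(node$carbon)) "?" else node$carbon
    self <- paste0(self, "(", node$anomer, cb, "-", p, ")")
  } else if (reduced) {
    self <- paste0(self, "-ol")
  }
  paste0(pre, self)
}

#' Serialise a glycan structure to canonical condensed text
#'
#' The canonical form lists, at every branch point, the lowest-numbered
#' linkage as the main chain and the remaining branches bracketed in
#' increasing linkage order, so `parse_structure(serialize_structure(s))`
#' reproduces `s`.
#'
#' @param s A `glycan_structure`.
#' @return Character string.
#' @export
serialize_structure <- function(s) {
  stopifnot(inherits(s, "glycan_structure"))
  .serialize_residue(s$root, TRUE, s$reduced)
}

#' @export
format.glycan_structure <- function(x, ...) x$text

#' @export
print.glycan_structure <- function(x, ...) {
  cat("<glycan_structure> ", x$text, "\n", sep = "")
  comp <- composition_of(x)
  cat("  composition: ", format(comp),
      "   core: ", classify_core(x), "\n", sep = "")
  invisible(x)
}

.walk_residues <- function(node, fun) {
  fun(node)
  for (k in node$children) .walk_residues(k, fun)
  invisible(NULL)
}

#' Composition of a parsed structure
#'
#' Counts residues by monosaccharide class; the reduced flag is carried
#' over.  (The text grammar does not encode sulfation, so the sulfate count
#' is always 0 here; sulfate is tracked at the composition level.)
#'
#' @param s A `glycan_structure`.
#' @return A [glycomp()] object.
#' @export
composition_of <- function(s) {
  stopifnot(inherits(s, "glycan_structure"))
  counts <- c(Hex = 0L, HexNAc = 0L, dHex = 0L, NeuAc = 0L)
  .walk_residues(s$root, function(n) {
    cls <- .residue_identities[[n$identity]]
    counts[[cls]] <<- counts[[cls]] + 1L
  })
  glycomp(Hex = counts[["Hex"]], HexNAc = counts[["HexNAc"]],
          dHex = counts[["dHex"]], NeuAc = counts[["NeuAc"]],
          reduced = s$reduced)
}

# core templates: residues directly attached to the GalNAc-ol root.
# each template row: identity, anomer, pos
.core_templates <- list(
  core1 = list(c("Gal", "b", 3)),
  core2 = list(c("Gal", "b", 3), c("GlcNAc", "b", 6)),
  core3 = list(c("GlcNAc", "b", 3)),
  core4 = list(c("GlcNAc", "b", 3), c("GlcNAc", "b", 6)),
  core5 = list(c("GalNAc", "a", 3)),
  core6 = list(c("GlcNAc", "b", 6)),
  core7 = list(c("GalNAc", "a", 6)),
  core8 = list(c("Gal", "a", 3))
)

.matches_slot <- function(node, tmpl) {
  id_ok <- node$identity == tmpl[[1]]
  ano_ok <- node$anomer == "?" || node$anomer == tmpl[[2]]
  pos_ok <- is.na(node$pos) || node$pos == as.integer(tmpl[[3]])
  id_ok && ano_ok && pos_ok
}

#' Classify the mucin O-glycan core of a reduced structure
#'
#' Matches the residues directly attached to the GalNAc-ol root against the
#' eight core templates (core 1: Gal b1-3; core 2: Gal b1-3 + GlcNAc b1-6;
#' core 3: GlcNAc b1-3; core 4: GlcNAc b1-3 + GlcNAc b1-6; core 5:
#' GalNAc a1-3; core 6: GlcNAc b1-6 alone; core 7: GalNAc a1-6; core 8:
#' Gal a1-3).  Extensions beyond the core residues do not change the label.
#' Unknown anomers/positions act as wildcards.
#'
#' @param s A reduced `glycan_structure`.
#' @param templates Core template list; see default for format.
#' @return Core label, `"core1"` .. `"core8"`, or `"unassigned"`
#'   (e.g. the bare Tn antigen GalNAc-ol).
#' @export
#' @examples
#' classify_core(parse_structure("Gal(b1-3)[GlcNAc(b1-6)]GalNAc-ol"))
classify_core <- function(s, templates = .core_templates) {
  stopifnot(inherits(s, "glycan_structure"))
  if (!s$reduced) stop("core classification requires a reduced structure")
  kids <- s$root$children
  for (label in names(templates)) {
    tmpl <- templates[[label]]
    if (length(kids) != length(tmpl)) next
    # each template slot must be matched by a distinct child
    used <- rep(FALSE, length(kids))
    ok <- TRUE
    for (slot in tmpl) {
      hit <- which(!used & vapply(kids, .matches_slot, logical(1),
                                  tmpl = slot))
      if (length(hit) == 0) { ok <- FALSE; break }
      used[hit[1]] <- TRUE
    }
    if (ok) return(label)
  }
  "unassigned"
}

.edge_list <- function(node, acc = list()) {
  for (k in node$children) {
    acc <- c(acc, list(list(parent = node, child = k)))
    acc <- .edge_list(k, acc)
  }
  acc
}

#' Detect structural motifs of an O-glycan
#'
#' Flags: `blood_group_H` (Fuc a1-2 on a Gal), `type_I_chain`
#' (Gal b1-3 GlcNAc), `type_II_chain` (Gal b1-4 GlcNAc), `LacNAc_extension`
#' (either chain type present), and the composition-level flags
#' `sialylated` / `fucosylated` (sulfation is not encoded in the structure
#' grammar and is reported from compositions).  Unknown anomer/position
#' match as wildcards.
#'
#' @param s A `glycan_structure`.
#' @return Named logical vector of motif flags plus a `core` attribute-free
#'   list: use [classify_core()] for the core.
#' @export
#' @examples
#' detect_motifs(parse_structure("Fuc(a1-2)Gal(b1-3)GalNAc-ol"))
detect_motifs <- function(s) {
  stopifnot(inherits(s, "glycan_structure"))
  edges <- .edge_list(s$root)
  has_edge <- function(child_id, ano, pos, parent_ids) {
    any(vapply(edges, function(e) {
      e$child$identity == child_id &&
        (e$child$anomer == "?" || e$child$anomer == ano) &&
        (is.na(e$child$pos) || e$child$pos == pos) &&
        e$parent$identity %in% parent_ids
    }, logical(1)))
  }
  comp <- composition_of(s)
  type1 <- has_edge("Gal", "b", 3, "GlcNAc")
  type2 <- has_edge("Gal", "b", 4, "GlcNAc")
  c(
    blood_group_H   = has_edge("Fuc", "a", 2, c("Gal")),
    type_I_chain    = type1,
    type_II_chain   = type2,
    LacNAc_extension = type1 || type2,
    sialylated      = comp$counts[["NeuAc"]] > 0,
    fucosylated     = comp$counts[["dHex"]] > 0,
    sulfated        = comp$sulfate > 0
  )
}
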