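# Shared helpers: independent mass oracle, random structure generator,
# canonical structure corpus.

# Independent residue/constant masses, typed in from the elemental
# formulas with a different atomic-mass table than the package uses
# (IUPAC 2021 values); agreement is expected to ~1e-5 Da.
oracle_masses <- list(
  Hex = 162.052824, HexNAc = 203.079373, dHex = 146.057909,
  NeuAc = 291.095417, S = 79.956815,
  water = 18.010565, red = 2.015650, proton = 1.007276
)

oracle_mz <- function(hex, hexnac, dhex, neuac, s, z = 1, reduced = TRUE) {
  m <- hex * oracle_masses$Hex + hexnac * oracle_masses$HexNAc +
    dhex * oracle_masses$dHex + neuac * oracle_masses$NeuAc +
    s * oracle_masses$S + oracle_masses$water +
    if (reduced) oracle_masses$red else 0
  (m - z * oracle_masses$proton) / z
}

# brute-force composition search over a full count lattice
oracle_search <- function(target_mz, z, tol_ppm, maxn = 6, min_hexnac = 1) {
  hits <- character(0)
  for (h in 0:maxn) for (n in min_hexnac:maxn) for (d in 0:maxn)
    for (a in 0:maxn) for (s in 0:2) {
      if (h + n + d + a < 1) next
      mz <- oracle_mz(h, n, d, a, s, z)
      if (abs((mz - target_mz) / target_mz * 1e6) <= tol_ppm) {
        hits <- c(hits, sprintf("H%d N%d F%d A%d S%d", h, n, d, a, s))
      }
    }
  sort(hits)
}

comp_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(sprintf("H%d N%d F%d A%d S%d",
               df$Hex, df$HexNAc, df$dHex, df$NeuAc, df$S))
}

# random O-glycan structure text: GalNAc-ol root, random extensions
random_structure_text <- function(n_extra = 4) {
  residues <- c("Gal", "GlcNAc", "GalNAc", "Fuc")
  anomers <- c("a", "b")
  # node list: each entry text fragments assembled at the end
  build <- function(depth) {
    name <- sample(residues, 1)
    ano <- sample(anomers, 1)
    pos <- sample(2:6, 1)
    kids <- ""
    if (depth > 0 && stats::runif(1) < 0.5) {
      k1 <- build(depth - 1)
      kids <- k1
      if (stats::runif(1) < 0.3) {
        repeat {
          k2 <- build(depth - 1)
          # distinct sibling linkage positions
          p1 <- sub(".*-(\\d)\\)$", "\\1", k1)
          p2 <- sub(".*-(\\d)\\)$", "\\1", k2)
          if (p1 != p2) { kids <- paste0(k1, "[", k2, "]"); break }
        }
      }
    }
    paste0(kids, name, "(", ano, "1-", pos, ")")
  }
  core <- sample(c("Gal(b1-3)", "GlcNAc(b1-3)", "GlcNAc(b1-6)"), 1)
  chain <- core
  for (i in seq_len(n_extra)) {
    if (stats::runif(1) < 0.6) chain <- paste0(build(1), chain) else break
  }
  paste0(chain, "GalNAc-ol")
}

structure_corpus <- c(
  "GalNAc-ol",
  "Gal(b1-3)GalNAc-ol",
  "Gal(a1-3)GalNAc-ol",
  "GlcNAc(b1-3)GalNAc-ol",
  "GlcNAc(b1-6)GalNAc-ol",
  "GalNAc(a1-3)GalNAc-ol",
  "GalNAc(a1-6)GalNAc-ol",
  "Gal(b1-3)[GlcNAc(b1-6)]GalNAc-ol",
  "GlcNAc(b1-3)[GlcNAc(b1-6)]GalNAc-ol",
  "Fuc(a1-2)Gal(b1-3)GalNAc-ol",
  "Fuc(a1-2)Gal(b1-3)[GlcNAc(b1-6)]GalNAc-ol",
  "Gal(b1-3)[Gal(b1-4)GlcNAc(b1-6)]GalNAc-ol",
  "Fuc(a1-2)Gal(b1-3)[Gal(b1-4)GlcNAc(b1-6)]GalNAc-ol",
  "Gal(b1-3)[Fuc(a1-2)Gal(b1-4)GlcNAc(b1-6)]GalNAc-ol",
  "Fuc(a1-2)Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)GalNAc-ol",
  "Fuc(a1-2)Gal(b1-3)GlcNAc(b1-3)Gal(b1-3)GalNAc-ol",
  "Neu5Ac(a2-3)Gal(b1-3)GalNAc-ol",
  "Neu5Ac(a2-3)Gal(b1-3)[GlcNAc(b1-6)]GalNAc-ol",
  "Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)GalNAc-ol",
  "Gal(b1-3)GlcNAc(b1-3)Gal(b1-3)GalNAc-ol",
  "Gal(b1-3)[Gal(b1-4)GlcNAc(b1-3)GlcNAc(b1-6)]GalNAc-ol",
  "Fuc(a1-2)Gal(b1-3)GlcNAc(b1-3)[GlcNAc(b1-6)]GalNAc-ol"
)

# the four m/z-895 isomer candidates (dHex1 Hex2 HexNAc2 alditols):
# two core 2 and two core 1 structures, all alpha-1,2-fucosylated
mz895_candidates <- function() {
  list(
    ccs273 = "Fuc(a1-2)Gal(b1-3)[Gal(b1-4)GlcNAc(b1-6)]GalNAc-ol",
    ccs275 = "Fuc(a1-2)Gal(b1-4)GlcNAc(b1-6)[Gal(b1-3)]GalNAc-ol",
    ccs290 = "Fuc(a1-2)Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)GalNAc-ol",
    ccs297 = "Fuc(a1-2)Gal(b1-3)GlcNAc(b1-3)Gal(b1-3)GalNAc-ol"
  )
}

# canonical synthetic TIMS calibration used across mobilogram tests
demo_tims_cal <- function() {
  g <- synth_calibrants("tims", list(slope = 1250), n_points = 8,
                        noise_rel = 0, seed = 99)
  fit_tims(g$points)
}
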