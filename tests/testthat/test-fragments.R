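test_that("glycosidic fragment masses match hand-derived ions", {
  s <- parse_structure(
    "Fuc(a1-2)Gal(b1-3)[Gal(b1-4)GlcNAc(b1-6)]GalNAc-ol")
  f <- generate_fragments(s, kinds = c("B", "C", "Y", "Z"))
  # loss of the terminal fucose as a Y ion
  y_fuc <- f[f$kind == "Y" & grepl("^Fuc", f$site), ]
  expect_equal(y_fuc$neutral, 750.290615, tolerance = 1e-5)
  expect_equal(y_fuc$mz, 749.283, tolerance = 1e-3)
  # B/C pairs differ by water, Y/Z pairs too
  for (site in unique(f$site)) {
    sub <- f[f$site == site, ]
    expect_equal(sub$neutral[sub$kind == "C"] -
                   sub$neutral[sub$kind == "B"],
                 mass_constants()[["water"]], tolerance = 1e-9)
    expect_equal(sub$neutral[sub$kind == "Y"] -
                   sub$neutral[sub$kind == "Z"],
                 mass_constants()[["water"]], tolerance = 1e-9)
  }
  # terminal Neu5Ac B ion
  s2 <- parse_structure("Neu5Ac(a2-3)Gal(b1-3)GalNAc-ol")
  b_neu <- generate_fragments(s2, kinds = "B")
  b_neu <- b_neu[grepl("^Neu5Ac", b_neu$site), ]
  expect_equal(b_neu$mz, 290.088, tolerance = 1e-3)
  # no glycosidic bonds -> empty
  expect_identical(
    nrow(generate_fragments(parse_structure("GalNAc-ol"),
                            kinds = c("B", "Y"))), 0L)
})

test_that("B+Y and C+Z reconstruct the parent mass for random trees", {
  set.seed(23)
  for (i in 1:100) {
    s <- parse_structure(random_structure_text())
    parent <- neutral_mass(composition_of(s))
    f <- generate_fragments(s, kinds = c("B", "C", "Y", "Z"))
    if (nrow(f) == 0) next
    # every B has a complementary Y and every C a complementary Z whose
    # neutral masses sum exactly to the parent
    pairs <- list(c("B", "Y"), c("C", "Z"))
    for (p in pairs) {
      left <- f$neutral[f$kind == p[1]]
      right <- f$neutral[f$kind == p[2]]
      for (b in left) {
        expect_true(any(abs(right - (parent - b)) < 1e-9),
                    info = paste(s$text, p[1], b))
      }
    }
  }
})

test_that("a linear n-residue chain yields 4(n-1) glycosidic fragments", {
  chains <- c(
    "Gal(b1-3)GalNAc-ol",
    "Gal(b1-4)GlcNAc(b1-3)GalNAc-ol",
    "Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)GalNAc-ol",
    "Fuc(a1-2)Gal(b1-4)GlcNAc(b1-3)Gal(b1-3)GalNAc-ol"
  )
  for (i in seq_along(chains)) {
    n <- i + 1
    f <- generate_fragments(parse_structure(chains[i]),
                            kinds = c("B", "C", "Y", "Z"),
                            max_cleavages = 1)
    expect_identical(nrow(f), as.integer(4 * (n - 1)), info = chains[i])
  }
})

test_that("double cleavages add internal fragments that stay positive", {
  s <- parse_structure(
    "Fuc(a1-2)Gal(b1-3)[Gal(b1-4)GlcNAc(b1-6)]GalNAc-ol")
  f1 <- generate_fragments(s, kinds = c("B", "C", "Y", "Z"),
                           max_cleavages = 1)
  f2 <- generate_fragments(s, kinds = c("B", "C", "Y", "Z"),
                           max_cleavages = 2)
  expect_gt(nrow(f2), nrow(f1))
  expect_true(all(f2$neutral > 0))
  expect_true(any(grepl("/", f2$kind)))
  # no duplicated (kind, neutral) pairs
  expect_false(any(duplicated(paste(f2$kind, round(f2$neutral, 6)))))
  expect_error(generate_fragments(s, max_cleavages = 3), "1 or 2")
})

test_that("spectrum annotation picks nearest candidates within ppm", {
  s <- parse_structure(
    "Fuc(a1-2)Gal(b1-3)[Gal(b1-4)GlcNAc(b1-6)]GalNAc-ol")
  f <- generate_fragments(s, kinds = c("B", "C", "Y", "Z"))
  m <- annotate_spectrum(data.frame(mz = 749.283, intensity = 100), f,
                         tol_ppm = 20)
  expect_identical(nrow(m), 1L)
  expect_identical(m$kind, "Y")
  expect_true(grepl("^Fuc", m$site))
  # far-off peak matches nothing; empty input gives empty output
  expect_identical(
    nrow(annotate_spectrum(data.frame(mz = 123.456, intensity = 10), f,
                           20)), 0L)
  expect_identical(
    nrow(annotate_spectrum(data.frame(mz = numeric(0),
                                      intensity = numeric(0)), f, 20)),
    0L)
  # tie-break: identical candidate masses resolve by kind order B < C < Y
  cand <- data.frame(kind = c("Y", "B"), site = c("y", "b"),
                     neutral = c(501.007276, 501.007276),
                     mz = c(500, 500), retains_alditol = c(TRUE, FALSE))
  tie <- annotate_spectrum(data.frame(mz = 500, intensity = 1), cand, 10)
  expect_identical(tie$kind, "B")
})

test_that("noiseless template spectra rank their own core first", {
  templates <- core_templates()
  rules <- derive_diagnostic_rules(templates)
  for (nm in names(templates)) {
    f <- generate_fragments(templates[[nm]])
    spec <- data.frame(mz = f$mz, intensity = 1)
    sc <- score_core_diagnostics(annotate_spectrum(spec, f, 10), rules)
    expect_identical(sc$label[1], nm)
    expect_false(attr(sc, "tie"))
  }
})

test_that("scoring flags empty and tied outcomes", {
  rules <- derive_diagnostic_rules()
  empty <- annotate_spectrum(
    data.frame(mz = numeric(0), intensity = numeric(0)),
    generate_fragments(core_templates()[[1]]), 10)
  sc <- score_core_diagnostics(empty, rules)
  expect_true(all(sc$score == 0))
  expect_false(attr(sc, "assigned"))
  # two labels with identical satisfied rules tie
  tied_rules <- list(
    list(name = "r1", required = 100, forbidden = numeric(0),
         implies = "core1", weight = 1),
    list(name = "r2", required = 100, forbidden = numeric(0),
         implies = "core2", weight = 1))
  m <- data.frame(peak_mz = 100, intensity = 1)
  sc2 <- score_core_diagnostics(m, tied_rules)
  expect_true(attr(sc2, "tie"))
  expect_error(score_core_diagnostics(m, list()), "empty")
})
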