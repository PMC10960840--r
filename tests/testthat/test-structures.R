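test_that("parse/serialize round-trips the canonical corpus", {
  for (txt in structure_corpus) {
    s <- parse_structure(txt)
    expect_identical(serialize_structure(s), txt, info = txt)
    # parse of the serialisation reproduces the tree
    expect_identical(parse_structure(serialize_structure(s)), s,
                     info = txt)
  }
})

test_that("parser handles branches, errors and canonical child order", {
  s <- parse_structure("Gal(b1-3)[GlcNAc(b1-6)]GalNAc-ol")
  expect_identical(s$root$identity, "GalNAc")
  expect_length(s$root$children, 2)
  expect_identical(vapply(s$root$children, `[[`, integer(1), "pos"),
                   c(3L, 6L))
  # bracket-first input is canonicalised to lowest-position main chain
  s2 <- parse_structure("GlcNAc(b1-6)[Gal(b1-3)]GalNAc-ol")
  expect_identical(s2$text, "Gal(b1-3)[GlcNAc(b1-6)]GalNAc-ol")
  expect_identical(parse_structure("GalNAc-ol")$text, "GalNAc-ol")
  expect_error(parse_structure("Gal(b1-3"), "parse error")
  expect_error(parse_structure("Gal(b1-3)]GalNAc-ol"), "parse error")
  expect_error(parse_structure("Qux(b1-3)GalNAc-ol"), "unknown residue")
  expect_error(parse_structure("Gal(b1-3)[Fuc(a1-3)]GalNAc-ol"),
               "duplicate linkage")
})

test_that("core classification follows the eight root templates", {
  cases <- list(
    c("Gal(b1-3)GalNAc-ol", "core1"),
    c("Gal(b1-3)[GlcNAc(b1-6)]GalNAc-ol", "core2"),
    c("GlcNAc(b1-3)GalNAc-ol", "core3"),
    c("GlcNAc(b1-3)[GlcNAc(b1-6)]GalNAc-ol", "core4"),
    c("GalNAc(a1-3)GalNAc-ol", "core5"),
    c("GlcNAc(b1-6)GalNAc-ol", "core6"),
    c("GalNAc(a1-6)GalNAc-ol", "core7"),
    c("Gal(a1-3)GalNAc-ol", "core8"),
    c("GalNAc-ol", "unassigned"),
    c("Fuc(a1-2)Gal(b1-3)GalNAc-ol", "core1"),
    c("Fuc(a1-2)Gal(b1-4)GlcNAc(b1-6)[Gal(b1-3)]GalNAc-ol", "core2")
  )
  for (cs in cases) {
    expect_identical(classify_core(parse_structure(cs[1])), cs[2],
                     info = cs[1])
  }
  expect_error(classify_core(parse_structure("Gal(b1-3)GalNAc")),
               "reduced")
})

test_that("core label is invariant under non-core extension", {
  set.seed(11)
  exts <- c("Gal(b1-4)", "Fuc(a1-2)", "Neu5Ac(a2-3)",
            "Gal(b1-4)GlcNAc(b1-3)")
  bases <- list(
    c("Gal(b1-3)GalNAc-ol", "core1"),
    c("Gal(b1-3)[GlcNAc(b1-6)]GalNAc-ol", "core2"),
    c("GlcNAc(b1-3)GalNAc-ol", "core3")
  )
  for (b in bases) {
    for (e in exts) {
      extended <- paste0(e, b[1])  # graft onto the leftmost terminal
      expect_identical(classify_core(parse_structure(extended)), b[2],
                       info = extended)
    }
  }
})

test_that("motif detection flags H antigen and chain types", {
  m <- detect_motifs(parse_structure("Fuc(a1-2)Gal(b1-3)GalNAc-ol"))
  expect_true(m[["blood_group_H"]])
  expect_true(m[["fucosylated"]])
  expect_false(m[["type_I_chain"]] || m[["type_II_chain"]])
  m2 <- detect_motifs(
    parse_structure("Gal(b1-3)[Gal(b1-4)GlcNAc(b1-6)]GalNAc-ol"))
  expect_true(m2[["type_II_chain"]])
  expect_true(m2[["LacNAc_extension"]])
  expect_false(m2[["type_I_chain"]])
  m3 <- detect_motifs(
    parse_structure("Fuc(a1-2)Gal(b1-3)GlcNAc(b1-3)Gal(b1-3)GalNAc-ol"))
  expect_true(m3[["type_I_chain"]])
  m4 <- detect_motifs(parse_structure("Gal(b1-3)GalNAc-ol"))
  expect_false(any(m4[c("blood_group_H", "type_I_chain", "type_II_chain",
                        "sialylated", "fucosylated", "sulfated")]))
  m5 <- detect_motifs(parse_structure("Neu5Ac(a2-3)Gal(b1-3)GalNAc-ol"))
  expect_true(m5[["sialylated"]])
})

test_that("structure composition is mass-consistent with the mass module", {
  s <- parse_structure(
    "Fuc(a1-2)Gal(b1-3)[Gal(b1-4)GlcNAc(b1-6)]GalNAc-ol")
  comp <- composition_of(s)
  expect_identical(format(comp), "Hex2HexNAc2dHex1-ol")
  expect_equal(round(glycan_mz(comp, 1)), 895)
  expect_identical(format(composition_of(parse_structure("GalNAc-ol"))),
                   "HexNAc1-ol")
  # random structures: node count matches residue-class counts
  set.seed(5)
  for (i in 1:20) {
    txt <- random_structure_text()
    cc <- composition_of(parse_structure(txt))
    n_tokens <- lengths(regmatches(txt, gregexpr("\\(", txt))) + 1L
    expect_identical(sum(cc$counts), as.integer(n_tokens), info = txt)
  }
})
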