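# Hairpin representation, design properties and the energy model.

test_that("hairpin construction enforces the invariants", {
  h <- hairpin("h", "GaUC", "aaaa", "gAUC", position = 7)  # mixed case + T ok
  expect_s3_class(h, "hairpin")
  expect_equal(h$stem5, "GAUC")
  expect_error(hairpin("h", "GGG", "AAAA", "CC"), "equal length")
  expect_error(hairpin("h", "GGGG", "AA", "CCCC"), "loop")
  expect_error(hairpin("h", "AAAA", "GAAA", "AAAA"), "not a closed stem")
  expect_error(hairpin("h", "GGGG", "GAAA", "CCCC", position = 0), "position")
  expect_error(sanitize_rna("ACGX"), "outside")
})

test_that("stem GC content counts the stem only", {
  expect_equal(stem_gc_content(hairpin("h", "GGGG", "GAAA", "CCCC")), 1.0)
  expect_equal(stem_gc_content(hairpin("h", "AUAU", "UUCG", "AUAU")), 0.0)
  expect_equal(stem_gc_content(hairpin("h", "GAUC", "AAAA", "GAUC")), 0.5)
})

test_that("GC classification uses the <0.40 / >0.75 thresholds", {
  expect_equal(classify_gc(0.80), "high")
  expect_equal(classify_gc(0.30), "low")
  expect_equal(classify_gc(0.50), "medium")
  expect_equal(classify_gc(0.40), "medium")  # boundaries are medium
  expect_equal(classify_gc(0.75), "medium")
  expect_error(classify_gc(-0.1))
  expect_error(classify_gc(1.1))
})

test_that("energy model tables satisfy their invariants", {
  m <- energy_model()
  wc <- c("AU", "UA", "GC", "CG")
  expect_true(all(m$stack[wc, wc] <= 0))
  expect_true(all(m$loop_init > 0))
  # 180-degree rotation symmetry of the full doublet table
  flip <- c(AU = "UA", UA = "AU", GC = "CG", CG = "GC", GU = "UG", UG = "GU")
  for (o in rownames(m$stack)) for (i in colnames(m$stack))
    expect_equal(m$stack[o, i], m$stack[flip[[i]], flip[[o]]])
  # log extrapolation beyond the table is continuous and increasing
  expect_gt(loop_init_dg(31), loop_init_dg(30))
  expect_lt(loop_init_dg(31) - loop_init_dg(30), 0.1)
})

test_that("hairpin_mfe equals a hand summation over the embedded tables", {
  m <- energy_model()
  h <- hairpin("h", "GGGG", "GAAA", "CCCC")
  # independent hand summation: three 5'GG3'/3'CC5' stacks + tetraloop init
  by_hand <- 3 * m$stack["GC", "GC"] + m$loop_init[["4"]]
  expect_equal(hairpin_mfe(h, m), by_hand)
  # AU ends are penalized at both helix termini
  h2 <- hairpin("h", "AGGA", "GAAA", "UCCU")
  by_hand2 <- m$stack["AU", "GC"] + m$stack["GC", "GC"] + m$stack["GC", "AU"] +
    m$loop_init[["4"]] + 2 * m$au_end
  expect_equal(hairpin_mfe(h2, m, clip = FALSE), by_hand2)
})

test_that("dG additivity: one more closing GC pair adds exactly one stack term", {
  m <- energy_model()
  h4 <- hairpin("h", "GGGG", "GAAA", "CCCC")
  h5 <- hairpin("h", "GGGGG", "GAAA", "CCCCC")
  expect_equal(hairpin_mfe(h5, m) - hairpin_mfe(h4, m), m$stack["GC", "GC"])
  expect_lt(hairpin_mfe(h5, m), hairpin_mfe(h4, m))  # strictly more stable
})

test_that("weak stems clip to the unfolded reference 0", {
  h <- hairpin("h", "AU", "AAAA", "AU")
  expect_gt(hairpin_mfe(h, clip = FALSE), 0)
  expect_equal(hairpin_mfe(h), 0)
})

test_that("structure_dg agrees with hairpin_mfe on the designed fold", {
  set.seed(42)
  for (i in 1:25) {
    h <- random_hairpin()
    expect_equal(structure_dg(hairpin_sequence(h), dot_bracket(h)),
                 hairpin_mfe(h, clip = FALSE))
  }
})

test_that("structure_dg scores a lone closing pair as loop init + terminal terms", {
  m <- energy_model()
  expect_equal(structure_dg("GAAAC", "(...)"), m$loop_init[["3"]])
  expect_equal(structure_dg("UAAAA", "(...)"), m$loop_init[["3"]] + 2 * m$au_end)
  expect_error(structure_dg("GAAC", "(..)"), "shorter than 3")
  expect_error(structure_dg("AAAAA", "(...)"), "cannot pair")
})

test_that("enumeration handles unstructured and short sequences", {
  e <- enumerate_mfe("AAAAAAAA")
  expect_equal(e$structure, "........")
  expect_equal(e$dg, 0)
  expect_equal(sequence_mfe("AAAAAAAAAAAA"), 0)
  expect_error(enumerate_mfe(strrep("GC", 20)), "too long")
})

test_that("enumeration is a true lower bound for the designed fold", {
  # oracle equivalence on random designed hairpins with random flanks
  set.seed(1203)
  n_equal <- 0L
  for (i in 1:60) {
    h <- random_hairpin(stem_len = sample(2:6, 1), loop_len = sample(3:5, 1))
    seq <- hairpin_sequence(h)
    if (nchar(seq) > 22) next
    e <- enumerate_mfe(seq)
    expect_lte(e$dg, hairpin_mfe(h) + 1e-9)
    if (e$structure == dot_bracket(h)) {
      n_equal <- n_equal + 1L
      expect_equal(e$dg, hairpin_mfe(h, clip = FALSE))
    }
    # cross-check the C++ evaluation with the independent R scorer
    expect_equal(structure_dg(seq, e$structure), e$dg, tolerance = 1e-9)
  }
  expect_gt(n_equal, 5L)  # the designed fold wins often enough to test equality
})

test_that("enumeration ties break toward fewer pairs", {
  # a sequence with no stabilizing structure keeps the open chain even though
  # zero-energy paired structures may exist
  e <- enumerate_mfe("GAAAACAAAGAAAC")
  if (e$dg == 0) expect_equal(e$structure, strrep(".", 14))
})

test_that("place_element positions the stem start at the stated coordinate", {
  h15 <- hairpin("h", "GGGG", "GAAA", "CCCC", position = 15)
  pe15 <- place_element(h15)
  expect_equal(pe15$spacer, "")
  expect_equal(nchar(pe15$leader), 14)

  h33 <- hairpin("h", "GGGG", "GAAA", "CCCC", position = 33)
  pe33 <- place_element(h33)
  expect_equal(pe33$spacer, strrep("CAA", 6))
  expect_equal(nchar(pe33$spacer), 18)

  h3 <- hairpin("h", "GGGG", "GAAA", "CCCC", position = 3)
  expect_equal(nchar(place_element(h3)$leader), 2)

  expect_error(place_element(hairpin("h", "GG", "AAA", "CC", position = 17)),
               "multiple of 3")
  expect_error(place_element(hairpin("h", "GG", "AAA", "CC", position = 2)),
               ">= 3")
})

test_that("placement round trip recovers the position", {
  for (pos in c(3, 7, 15, 33)) {
    h <- hairpin("h", "GGCC", "GAAA", "GGCC", position = pos)
    pe <- place_element(h)
    expect_equal(parse_placed_element(pe$full_utr, h), pos)
  }
})

test_that("stem swap with reversal preserves the GC fraction", {
  set.seed(99)
  for (i in 1:20) {
    h <- random_hairpin()
    rev_str <- function(s) paste(rev(.subset2(strsplit(s, ""), 1)), collapse = "")
    h2 <- hairpin(h$name, rev_str(h$stem3), h$loop, rev_str(h$stem5))
    expect_equal(stem_gc_content(h2), stem_gc_content(h))
  }
})

test_that("design_stem hits target dG and GC class deterministically", {
  h <- design_stem(-30, "high", tol = 0.5, seed = 11)
  expect_lte(abs(hairpin_mfe(h) - (-30)), 0.5)
  expect_equal(classify_gc(stem_gc_content(h)), "high")
  h_again <- design_stem(-30, "high", tol = 0.5, seed = 11)
  expect_identical(hairpin_sequence(h_again), hairpin_sequence(h))

  h0 <- design_stem(0, "medium", tol = 0.5, seed = 1)
  expect_lte(abs(hairpin_mfe(h0)), 0.5)

  expect_error(design_stem(-1000, "high", seed = 1), "unreachable")

  # a low-GC -30 stem either satisfies both constraints or fails loudly
  res <- tryCatch(design_stem(-30, "low", tol = 0.5, seed = 2),
                  error = function(e) e)
  if (inherits(res, "hairpin")) {
    expect_lte(abs(hairpin_mfe(res) + 30), 0.5)
    expect_equal(classify_gc(stem_gc_content(res)), "low")
  } else {
    expect_match(conditionMessage(res), "unreachable")
  }
})

test_that("FASTA and property-table round trips preserve the elements", {
  hs <- list(hairpin("el1", "GGGG", "GAAA", "CCCC", position = 15),
             hairpin("el2", "AUGC", "UUCG", "GCAU", position = 33))
  f <- tempfile(fileext = ".fasta")
  write_hairpin_fasta(hs, f)
  back <- read_hairpin_fasta(f)
  expect_equal(vapply(back, hairpin_sequence, ""), vapply(hs, hairpin_sequence, ""))
  expect_equal(vapply(back, function(h) h$position, 1L), c(15L, 33L))

  tab <- hairpin_property_table(hs)
  expect_named(tab, c("name", "dg_kcal_mol", "gc_fraction", "gc_class", "position"))
  expect_equal(tab$gc_class, c("high", "medium"))
})
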