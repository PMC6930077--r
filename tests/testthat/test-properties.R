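test_that("hydrophobicity matches hand-summed Kyte-Doolittle values", {
  expect_equal(hydrophobicity("AAA"), 1.8)
  expect_equal(hydrophobicity("IR"), 0.0)
  expect_equal(hydrophobicity("CASSF"),
               mean(c(2.5, 1.8, -0.8, -0.8, 2.8)))
  expect_equal(hydrophobicity("CASSF", method = "sum"),
               sum(c(2.5, 1.8, -0.8, -0.8, 2.8)))
  expect_error(hydrophobicity(""), "empty")
  expect_error(hydrophobicity("ABZ"), "invalid")
})

test_that("hydrophobicity is linear under concatenation", {
  set.seed(61)
  peps <- random_peptides(20)
  for (i in seq(1, 19, by = 2)) {
    a <- peps[i]; b <- peps[i + 1]
    combined <- hydrophobicity(paste0(a, b))
    parts <- (nchar(a) * hydrophobicity(a) + nchar(b) * hydrophobicity(b)) /
      (nchar(a) + nchar(b))
    expect_equal(combined, parts)
  }
})

test_that("ambiguous X residues are neutral and warned about", {
  expect_warning(h <- hydrophobicity("AXA"), "X")
  expect_equal(h, (1.8 + 0 + 1.8) / 3)
  expect_warning(f <- residue_class_freqs("DX"), "X")
  expect_equal(f$polar, 1.0)  # X excluded from the denominator
})

test_that("pI reproduces symmetric and monotone cases", {
  expect_equal(isoelectric_point("GGG"), 6.100, tolerance = 1e-6)
  expect_gt(isoelectric_point("K"), isoelectric_point("D"))
})

test_that("pI bisection agrees with a 1e-4 grid-search oracle", {
  set.seed(62)
  peps <- random_peptides(1000)
  pis <- isoelectric_point(peps)
  oracle <- vapply(peps, oracle_pi_grid, 0, USE.NAMES = FALSE)
  expect_lt(max(abs(pis - oracle)), 2e-4)
})

test_that("residue classes follow the printed definition, H in two classes", {
  f <- residue_class_freqs("DAVF")
  expect_equal(unlist(f), c(polar = 0.25, aliphatic = 0.50, aromatic = 0.25))
  fh <- residue_class_freqs("H")
  expect_equal(fh$polar, 1.0)
  expect_equal(fh$aromatic, 1.0)
  expect_equal(unname(unlist(residue_class_freqs("GGGG"))), c(0, 0, 0))
  # G and P are in no class: adding them changes no class count
  base <- residue_class_freqs("DAVF")
  padded <- residue_class_freqs("DAVFGP")
  expect_equal(unlist(padded) * 6, unlist(base) * 4)
})

test_that("length distribution reports smallest-wins modes", {
  ld <- length_distribution(c("AAAAAAAAAAAAAA", "AAAAAAAAAAAAAA",
                              "AAAAAAAAAAAAAAA"))
  expect_equal(ld$mode, 14L)
  expect_equal(sum(ld$freq), 1)
  tie <- length_distribution(c(strrep("A", 14), strrep("A", 15)))
  expect_equal(tie$mode, 14L)
  expect_error(length_distribution(character(0)), "empty")
})

test_that("PFM columns are stochastic with bounded information content", {
  set.seed(63)
  seqs <- random_peptides(200, min_len = 12, max_len = 16)
  pfm <- position_frequency_matrix(seqs, 14)
  expect_equal(colSums(pfm$pfm), setNames(rep(1, 14), as.character(1:14)),
               tolerance = 1e-9)
  expect_true(all(pfm$ic >= 0 & pfm$ic <= log2(20) + 1e-12))
  expect_equal(pfm$n_kept, sum(nchar(seqs) == 14))
  expect_error(position_frequency_matrix(seqs, 40), "no sequence")
})

test_that("degenerate columns reach the IC extremes", {
  all_c <- position_frequency_matrix(rep("CCCC", 10), 4)
  expect_equal(all_c$ic, setNames(rep(log2(20), 4), 1:4))
  uniform <- position_frequency_matrix(names(KD_SCALE), 1)
  expect_equal(unname(uniform$ic), 0)
})

test_that("a canonical-alpha-only repertoire gives a maximal logo", {
  sim <- simulate_repertoire(
    tissue_preset("spleen", canonical_alpha_fraction = 1), 100, seed = 64)
  rec <- sim$rearrangements
  aa <- rec$junction_aa[rec$locus == "TRA"]
  pfm <- position_frequency_matrix(aa, 15)
  expect_equal(pfm$n_kept, 100L)
  expect_equal(unname(pfm$ic), rep(log2(20), 15))
  expect_identical(pfm$consensus, CANONICAL_CDR3A)
})
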