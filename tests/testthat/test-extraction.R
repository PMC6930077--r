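germ <- toy_germline()

mutate_at <- function(seq, pos) {
  other <- setdiff(c("A", "C", "G", "T"), substr(seq, pos, pos))
  substr(seq, pos, pos) <- sample(other, 1)
  seq
}

test_that("V assignment matches constructed reads and tolerates mutations", {
  set.seed(31)
  g <- generate_cdr3_nt("TRBV13-2", "TRBJ2-7", 14, germline = germ)
  v <- germ$v_segments[germ$v_segments$gene == "TRBV13-2", ]
  read <- paste0(substr(v$sequence, 1, v$cys_anchor), g$junction)
  res <- assign_v(read, germ)
  expect_identical(res$v_call, "TRBV13-2")
  expect_identical(res$mismatches, 0L)
  expect_identical(res$cys_offset, 54L)

  res1 <- assign_v(mutate_at(read, 20L), germ)
  expect_identical(res1$v_call, "TRBV13-2")
  expect_identical(res1$mismatches, 1L)

  random_read <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                       collapse = "")
  # exhaustive check: no reference prefix is within tolerance
  prefix_mm <- vapply(seq_len(nrow(germ$v_segments)), function(i) {
    p <- substr(germ$v_segments$sequence[i], 1,
                germ$v_segments$cys_anchor[i] + 3)
    sum(utf8ToInt(substr(random_read, 1, nchar(p))) != utf8ToInt(p))
  }, numeric(1))
  expect_true(min(prefix_mm) > 2)
  expect_true(is.na(assign_v(random_read, germ)$v_call))
})

test_that("J anchor location round-trips ground truth and tracks shifts", {
  set.seed(32)
  sim <- simulate_repertoire("spleen", 30, seed = 33)
  rec <- sim$rearrangements
  j <- germ$j_segments
  for (i in sample(nrow(rec), 10)) {
    jrow <- j[j$gene == rec$j_call[i], ]
    expected <- nchar(rec$sequence[i]) - (nchar(jrow$sequence) -
                                            jrow$phe_anchor)
    expect_identical(
      locate_j_anchor(rec$sequence[i], germ, rec$j_call[i]), expected)
  }
  read <- rec$sequence[1]
  shifted <- paste0(substr(read, 1, 60), "AC", substr(read, 61, nchar(read)))
  expect_identical(locate_j_anchor(shifted, germ, rec$j_call[1]),
                   locate_j_anchor(read, germ, rec$j_call[1]) + 2L)
  truncated <- substr(read, 1, nchar(read) - 55)
  expect_true(is.na(locate_j_anchor(truncated, germ, rec$j_call[1])))
})

test_that("junction extraction is inclusive anchor-to-anchor arithmetic", {
  seq <- paste(rep("ACGT", 20), collapse = "")
  expect_equal(nchar(extract_junction(seq, 12, 33)), 24L)
  expect_equal(extract_junction(seq, 12, 12), substr(seq, 13, 15))
  expect_error(extract_junction(seq, 33, 12), "precede")
})

test_that("productivity is frame plus stop-free translation", {
  res <- classify_productive("TGTGCAAGCAGTTTT")
  expect_true(res$productive)
  expect_identical(res$junction_aa, "CASSF")
  out_of_frame <- classify_productive(strrep("AC", 7))  # 14 nt
  expect_false(out_of_frame$productive)
  expect_identical(out_of_frame$junction_aa, "")
  with_stop <- classify_productive("TGTTAATTT")
  expect_false(with_stop$productive)
  # conjunction of the two independent predicates
  set.seed(8)
  junctions <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(9:15, 1), replace = TRUE),
          collapse = ""), "")
  res <- classify_productive(junctions)
  in_frame <- nchar(junctions) %% 3L == 0L
  stop_free <- rep(FALSE, 50)
  stop_free[in_frame] <- !grepl("\\*", oracle_translate(junctions[in_frame]))
  expect_identical(res$productive, in_frame & stop_free)
})

test_that("extraction recovers generator ground truth exactly", {
  sim <- simulate_repertoire("iLN", 1000, seed = 41)
  ext <- extract_rearrangements(sim$rearrangements, germ)
  expect_equal(nrow(ext$rejects), 0L)
  truth <- sim$truth[match(ext$rearrangements$sequence_id,
                           sim$truth$sequence_id), ]
  expect_identical(ext$rearrangements$v_call, truth$true_v_call)
  expect_identical(ext$rearrangements$j_call, truth$true_j_call)
  expect_identical(ext$rearrangements$junction, truth$true_junction)
  expect_identical(ext$rearrangements$productive, truth$true_productive)
})

test_that("lightly mutated reads keep their assignments", {
  set.seed(42)
  sim <- simulate_repertoire("spleen", 100, seed = 43)
  rec <- sim$rearrangements
  mutated <- vapply(seq_len(nrow(rec)), function(i)
    mutate_at(rec$sequence[i], sample(30L, 1)), "")
  ext <- extract_rearrangements(
    data.frame(sequence_id = rec$sequence_id, sequence = mutated,
               stringsAsFactors = FALSE), germ)
  expect_equal(nrow(ext$rejects), 0L)
  expect_identical(ext$rearrangements$v_call, rec$v_call)
})

test_that("unassignable reads land in rejects with a reason", {
  sim <- simulate_repertoire("spleen", 5, seed = 44)
  reads <- c(sim$rearrangements$sequence[1],
             paste(rep("A", 130), collapse = ""))
  ext <- extract_rearrangements(reads, germ)
  expect_equal(nrow(ext$rearrangements), 1L)
  expect_equal(nrow(ext$rejects), 1L)
  expect_true(ext$rejects$reason %in%
                c("v_unassignable", "j_unassignable",
                  "anchor_motif_not_found"))
})

test_that("clonotype assembly groups by V + junction and conserves counts", {
  rec <- data.frame(
    sequence_id = sprintf("r%d", 1:4),
    sequence = "", v_call = c("TRBV29", "TRBV29", "TRBV13-2", "TRBV29"),
    d_call = "", j_call = "TRBJ1-1",
    junction = c("TGTAAATTT", "TGTAAATTT", "TGTAAATTT", "TGTCCCTTT"),
    junction_aa = c("CKF", "CKF", "CKF", "CPF"),
    productive = TRUE, duplicate_count = c(2L, 3L, 1L, 4L),
    locus = "TRB", sample_id = "s1", tissue = "spleen",
    stringsAsFactors = FALSE
  )
  cl <- assemble_clonotypes(rec, scope = "pooled")
  expect_equal(nrow(cl), 3L)
  expect_equal(cl$count[cl$v_call == "TRBV29" & cl$cdr3_nt == "TGTAAATTT"],
               5L)
  # same junction under a different V is a different clonotype
  expect_equal(sum(cl$cdr3_nt == "TGTAAATTT"), 2L)
  expect_equal(sum(cl$count), sum(rec$duplicate_count))
})

test_that("assembly matches ground-truth clonotype counts on generator data", {
  sim <- simulate_repertoire("mLN", 800, seed = 45)
  rec <- sim$rearrangements
  trb <- rec[rec$locus == "TRB" & rec$productive, ]
  cl <- suppressMessages(assemble_clonotypes(rec[rec$locus == "TRB", ],
                                             scope = "pooled"))
  truth_keys <- unique(paste(trb$v_call, trb$junction))
  expect_equal(nrow(cl), length(truth_keys))
  expect_equal(sum(cl$count), sum(trb$duplicate_count))
  # sorted by count descending
  expect_true(all(diff(cl$count) <= 0))
})
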