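toy_clonotypes <- function(v, count, j = "TRBJ1-1", aa = NULL, nt = NULL) {
  n <- length(v)
  data.frame(v_call = v, j_call = rep_len(j, n),
             cdr3_nt = if (is.null(nt)) sprintf("TGT%03dTTT", seq_len(n))
             else nt,
             cdr3_aa = if (is.null(aa)) sprintf("CX%dF", seq_len(n)) else aa,
             count = as.integer(count), sample_id = "s1", tissue = "spleen",
             stringsAsFactors = FALSE)
}

test_that("V usage normalises under both weightings", {
  cl <- toy_clonotypes(c("TRBV29", "TRBV13-2"), c(5, 5))
  expect_equal(v_usage(cl, "count"),
               c("TRBV13-2" = 0.5, "TRBV29" = 0.5))
  cl2 <- toy_clonotypes(c("TRBV29", "TRBV29"), c(1, 9))
  expect_equal(v_usage(cl2, "count"), c(TRBV29 = 1.0))
  expect_equal(v_usage(cl2, "clonotype"), c(TRBV29 = 1.0))
  cl3 <- toy_clonotypes(c("TRBV29", "TRBV1"), c(9, 1))
  expect_equal(unname(v_usage(cl3, "clonotype")), c(0.5, 0.5))
  expect_equal(v_usage(cl3, "count")[["TRBV29"]], 0.9)
  expect_error(v_usage(cl3[0, ]), "empty")
})

test_that("V-J pairing percentages sum to 100 and marginalise to V usage", {
  cl <- toy_clonotypes(c("TRBV29", "TRBV29", "TRBV1", "TRBV13-2"),
                       c(1, 1, 1, 1),
                       j = c("TRBJ2-7", "TRBJ2-7", "TRBJ1-1", "TRBJ2-1"))
  m <- vj_pairing(cl)
  expect_equal(sum(m), 100)
  expect_equal(m["TRBV29", "TRBJ2-7"], 50)
  one <- vj_pairing(toy_clonotypes("TRBV29", 7))
  expect_equal(as.vector(one), 100)
  # marginalisation identity on generated data
  cl_big <- cached_clonotypes("spleen")
  m_big <- vj_pairing(cl_big)
  expect_equal(rowSums(m_big), 100 * v_usage(cl_big, "count"),
               tolerance = 1e-9)
  expect_equal(sum(m_big), 100, tolerance = 1e-6)
})

test_that("clone-size classes follow the 1/2/3/4/5+ binning", {
  cl <- toy_clonotypes(rep("TRBV29", 6), c(1, 1, 2, 3, 5, 7))
  expect_equal(clone_size_classes(cl),
               c("1" = 2 / 6, "2" = 1 / 6, "3" = 1 / 6, "4" = 0,
                 "5+" = 2 / 6))
  all1 <- clone_size_classes(toy_clonotypes(rep("TRBV1", 4), rep(1, 4)))
  expect_equal(unname(all1), c(1, 0, 0, 0, 0))
})

test_that("median count handles even and odd sizes", {
  expect_equal(median_count(toy_clonotypes(rep("V", 3), c(1, 1, 2))), 1)
  expect_equal(median_count(toy_clonotypes(rep("V", 4), c(1, 2, 3, 10))),
               2.5)
})

test_that("top-N cumulative frequency is a monotone clonality curve", {
  cl <- toy_clonotypes(rep("V", 3), c(5, 3, 2))
  expect_equal(top_n_cumulative(cl, 2), 0.8)
  expect_equal(top_n_cumulative(cl, 10), 1.0)
  expect_error(top_n_cumulative(cl, 0), "n")
  cl_big <- cached_clonotypes("iLN")
  curve <- vapply(c(1, 5, 25, 100, nrow(cl_big)),
                  function(k) top_n_cumulative(cl_big, k), 0)
  expect_true(all(diff(curve) >= 0))
  expect_equal(curve[length(curve)], 1)
})

test_that("more clonal presets give larger median and top-25 occupancy", {
  spleen <- cached_clonotypes("spleen")
  iln <- cached_clonotypes("iLN")
  expect_gte(median_count(iln), median_count(spleen))
  expect_gt(top_n_cumulative(iln, 25), top_n_cumulative(spleen, 25))
})

test_that("singleton fractions recover the log-series closed form", {
  for (tissue in c("spleen", "mLN", "iLN")) {
    cl <- cached_clonotypes(tissue)
    p1 <- logseries_singleton_fraction(tissue_preset(tissue)$theta)
    se <- sqrt(p1 * (1 - p1) / nrow(cl))
    expect_lt(abs(clone_size_classes(cl)[["1"]] - p1), 3 * se)
  }
})

test_that("rare-vs-abundant usage recovers a planted expansion bias", {
  cl <- toy_clonotypes(c("TRBV29", "TRBV29", "TRBV13-2"), c(1, 3, 1))
  res <- rare_vs_abundant_usage(cl, 2)
  expect_equal(res$rare, c("TRBV13-2" = 0.5, "TRBV29" = 0.5))
  expect_equal(res$abundant, c(TRBV29 = 1.0))
  expect_warning(
    res0 <- rare_vs_abundant_usage(toy_clonotypes("TRBV1", 1), 2),
    "abundant")
  expect_length(res0$abundant, 0L)
  # planted signal: expanded clones forced to TRBV29
  set.seed(55)
  cl_big <- cached_clonotypes("mLN")
  planted <- cl_big
  planted$v_call[planted$count >= 2] <- "TRBV29"
  res_big <- rare_vs_abundant_usage(planted, 2)
  expect_gt(res_big$abundant[["TRBV29"]], res_big$rare[["TRBV29"]])
})

test_that("statistics are invariant under record-order permutation", {
  set.seed(56)
  cl <- cached_clonotypes("spleen", n = 20000L)[1:500, ]
  shuffled <- cl[sample(nrow(cl)), ]
  expect_equal(v_usage(cl), v_usage(shuffled))
  expect_equal(vj_pairing(cl), vj_pairing(shuffled))
  expect_equal(clone_size_classes(cl), clone_size_classes(shuffled))
  expect_equal(top_n_cumulative(cl, 25), top_n_cumulative(shuffled, 25))
})

test_that("repertoire summary bundles consistent components", {
  cl <- cached_clonotypes("mLN")
  s <- summarize_repertoire(cl, top_n = 25)
  expect_s3_class(s, "repertoire_summary")
  expect_equal(sum(s$v_usage), 1, tolerance = 1e-9)
  expect_equal(sum(s$j_usage), 1, tolerance = 1e-9)
  expect_equal(sum(s$size_classes), 1, tolerance = 1e-9)
  expect_equal(sum(s$vj_pairing), 100, tolerance = 1e-6)
  expect_equal(s$singleton_fraction, s$size_classes[["1"]])
  expect_true(all(diff(s$top_n_cumulative) >= 0))
  expect_output(print(s), "singleton fraction")
})
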