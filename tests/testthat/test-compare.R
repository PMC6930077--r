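test_that("Mann-Whitney U and exact p match hand enumeration", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p, 2 / 6)
  sym <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(sym$U, 4.5)  # n_a * n_b / 2 under exchangeability
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("exact Mann-Whitney equals brute-force enumeration with ties", {
  set.seed(71)
  for (rep in 1:25) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- sample(1:4, na, replace = TRUE)  # small support forces ties
    b <- sample(1:4, nb, replace = TRUE)
    mine <- mann_whitney(a, b, mode = "exact")
    oracle <- oracle_mw_exact(a, b)
    expect_equal(mine$U, oracle$U)
    expect_equal(mine$p, oracle$p)
    # conservation: U(a,b) + U(b,a) = na * nb
    expect_equal(mine$U + mann_whitney(b, a)$U, na * nb)
  }
})

test_that("exact Mann-Whitney matches wilcox.test on tie-free data", {
  set.seed(72)
  for (rep in 1:10) {
    a <- sample(1:100, 6); b <- sample(101:200, 5) - 50
    if (length(intersect(a, b)) > 0) next
    mine <- mann_whitney(a, b, mode = "exact")
    ht <- wilcox.test(a, b, exact = TRUE)
    expect_equal(mine$U, unname(ht$statistic))
    expect_equal(mine$p, ht$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact p at moderate n", {
  set.seed(73)
  for (rep in 1:10) {
    a <- rnorm(7); b <- rnorm(7, 0.5)
    p_exact <- mann_whitney(a, b, mode = "exact")$p
    p_norm <- mann_whitney(a, b, mode = "normal")$p
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("t-test wrapper handles paired, Welch and degenerate inputs", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  res <- t_test(x, x, paired = TRUE)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_error(t_test(rep(0, 4), rep(1, 4)), "degenerate")
  expect_error(t_test(1:3, 1:4, paired = TRUE), "equal sample lengths")
  set.seed(74)
  a <- rnorm(10); b <- rnorm(10, 1)
  res <- t_test(a, b)
  ref <- t.test(a, b)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$df, unname(ref$parameter))
  # p agrees with direct quadrature of the t density
  quad <- 2 * integrate(dt, abs(res$t), Inf, df = res$df,
                        rel.tol = 1e-10)$value
  expect_equal(res$p, quad, tolerance = 1e-6)
})

test_that("two-group ANOVA reduces to the squared pooled t statistic", {
  set.seed(75)
  a <- rnorm(8); b <- rnorm(6, 0.3)
  an <- one_way_anova(c(a, b), rep(c("g1", "g2"), c(8, 6)), tukey = FALSE)
  tt <- t_test(a, b, equal_variance = TRUE)
  expect_equal(an$F, tt$t^2, tolerance = 1e-12)
  expect_equal(an$p, tt$p, tolerance = 1e-12)
  expect_error(one_way_anova(rep(1, 6), rep(c("a", "b"), 3)), "degenerate")
  expect_error(one_way_anova(rnorm(3), c("a", "a", "b")), "n >= 2")
})

test_that("ANOVA and Tukey HSD agree with aov/TukeyHSD", {
  set.seed(76)
  values <- rnorm(24, rep(c(0, 0.5, 1), each = 8))
  groups <- rep(c("g1", "g2", "g3"), each = 8)
  mine <- one_way_anova(values, groups)
  fit <- aov(values ~ groups)
  ref_f <- summary(fit)[[1]]
  expect_equal(mine$F, ref_f[["F value"]][1], tolerance = 1e-10)
  expect_equal(mine$p, ref_f[["Pr(>F)"]][1], tolerance = 1e-10)
  ref_tukey <- TukeyHSD(fit)$groups
  expect_equal(mine$tukey$p_adj,
               unname(ref_tukey[mine$tukey$comparison, "p adj"]),
               tolerance = 1e-8)
})

test_that("ANOVA type-I error is calibrated at the nominal level", {
  set.seed(77)
  rejections <- vapply(seq_len(10000), function(i) {
    v <- rnorm(15)
    one_way_anova(v, rep(c("a", "b", "c"), each = 5),
                  tukey = FALSE)$p < 0.05
  }, NA)
  expect_gte(mean(rejections), 0.045)
  expect_lte(mean(rejections), 0.055)
})

test_that("Pearson wrapper reproduces exact linear cases", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6))$r, 1.0)
  expect_equal(pearson_cor(c(1, 2, 3), -c(1, 2, 3))$r, -1.0)
  expect_error(pearson_cor(rep(1, 5), rnorm(5)), "variance")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("Pearson p-values are uniform under the null", {
  set.seed(78)
  ps <- vapply(seq_len(10000), function(i)
    pearson_cor(rnorm(20), rnorm(20))$p, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
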