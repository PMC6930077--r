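# Group-comparison statistics used in repertoire studies, with exact
# small-sample behaviour: Mann-Whitney with exact enumeration over group
# assignments (handles ties), t-tests, one-way ANOVA with Tukey HSD via the
# studentized-range distribution, and Pearson correlation.

#' Mann-Whitney U test
#'
#' `U = sum over pairs of 1(a > b) + 0.5 * 1(a == b)`. In exact mode the
#' two-sided p-value is computed by enumerating all `choose(na+nb, na)`
#' equally likely group assignments of the pooled values (valid under ties),
#' as `min(1, 2 * min(P(U* <= U), P(U* >= U)))`. Exact mode is used
#' automatically when `na + nb <= 14`; otherwise a tie-corrected normal
#' approximation with continuity correction is applied.
#'
#' @param a,b Numeric samples.
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @return List with `U` (statistic of sample `a`), `p` (two-sided) and
#'   `method`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks handle ties
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (mode == "auto") mode <- if (na + nb <= 14L) "exact" else "normal"
  if (mode == "exact") {
    sets <- combn(na + nb, na)
    u_all <- colSums(matrix(r[sets], nrow = na)) - na * (na + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= u_obs + eps),
                        mean(u_all >= u_obs - eps)))
    method <- "exact enumeration"
  } else {
    n <- na + nb
    mu <- na * nb / 2
    ties <- table(pooled)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      cc <- if (u_obs == mu) 0 else 0.5 * sign(u_obs - mu)
      z <- (u_obs - mu - cc) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation (tie + continuity corrected)"
  }
  list(U = u_obs, p = p, method = method)
}

#' Two-sample t-test
#'
#' Thin wrapper around [stats::t.test()]: paired or unpaired, with the
#' Welch degrees of freedom as the unpaired default (pooled variance via
#' `equal_variance = TRUE`). Degenerate inputs (zero variance everywhere)
#' are flagged as errors, except the paired-identical case, which returns
#' `t = 0, p = 1`.
#'
#' @param a,b Numeric samples; equal length required when `paired`.
#' @param paired Paired test (default FALSE).
#' @param equal_variance Pooled-variance unpaired test (default FALSE,
#'   i.e. Welch).
#' @return List with `t`, `df`, `p` and `method`.
#' @export
t_test <- function(a, b, paired = FALSE, equal_variance = FALSE) {
  if (paired) {
    if (length(a) != length(b)) {
      stop("paired mode requires equal sample lengths")
    }
    if (length(a) < 2L) stop("paired mode requires n >= 2")
    d <- a - b
    if (var(d) == 0) {
      if (all(d == 0)) {
        return(list(t = 0, df = length(a) - 1L, p = 1,
                    method = "paired t-test (identical samples)"))
      }
      stop("degenerate paired data: constant nonzero differences")
    }
    ht <- stats::t.test(a, b, paired = TRUE)
  } else {
    if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
    if (var(a) == 0 && var(b) == 0) {
      stop("degenerate data: zero variance in both samples")
    }
    ht <- stats::t.test(a, b, var.equal = equal_variance)
  }
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, method = ht$method)
}

#' One-way ANOVA with Tukey HSD
#'
#' Standard between/within variance decomposition. Tukey honestly
#' significant difference p-values are computed from the studentized-range
#' distribution ([stats::ptukey()], numerical integration) with the
#' Tukey-Kramer standard error for unbalanced groups.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (coerced to factor); at least 2 groups of
#'   at least 2 observations each.
#' @param tukey Also compute pairwise Tukey comparisons (default TRUE).
#' @return List with `F`, `df1`, `df2`, `p`, `method` and (optionally)
#'   `tukey`, a data frame of pairwise differences, q statistics and
#'   adjusted p-values.
#' @export
one_way_anova <- function(values, groups, tukey = TRUE) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ni <- tabulate(groups)
  if (k < 2L) stop("need at least 2 groups")
  if (any(ni < 2L)) stop("every group needs n >= 2")
  n <- length(values)
  means <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(ni * (means - grand)^2)
  ssw <- sum((values - means[as.integer(groups)])^2)
  df1 <- k - 1L
  df2 <- n - k
  if (ssw == 0) stop("degenerate data: zero within-group variance")
  msw <- ssw / df2
  f <- (ssb / df1) / msw
  out <- list(F = f, df1 = df1, df2 = df2,
              p = pf(f, df1, df2, lower.tail = FALSE),
              method = paste("one-way ANOVA;",
                             "Tukey HSD via studentized-range integration"))
  if (tukey) {
    pairs <- combn(levels(groups), 2)
    out$tukey <- data.frame(
      comparison = paste(pairs[2, ], pairs[1, ], sep = "-"),
      diff = means[pairs[2, ]] - means[pairs[1, ]],
      q = NA_real_, p_adj = NA_real_, row.names = NULL,
      stringsAsFactors = FALSE
    )
    for (i in seq_len(ncol(pairs))) {
      n1 <- ni[match(pairs[1, i], levels(groups))]
      n2 <- ni[match(pairs[2, i], levels(groups))]
      se <- sqrt(msw / 2 * (1 / n1 + 1 / n2))
      q <- abs(out$tukey$diff[i]) / se
      out$tukey$q[i] <- q
      out$tukey$p_adj[i] <- ptukey(q, k, df2, lower.tail = FALSE)
    }
  }
  out
}

#' Pearson correlation test
#'
#' Thin wrapper around [stats::cor.test()]: product-moment correlation
#' with a two-sided p-value from the t transform on n - 2 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `df`, `p` and `method`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (var(x) == 0 || var(y) == 0) stop("zero variance input")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), df = unname(ht$parameter),
       p = ht$p.value, method = ht$method)
}
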