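# Logarithmic-series clone-size model.
#
# p_k = theta^k / (k * (-log(1 - theta))), k = 1, 2, ...
# The singleton fraction p_1 = theta / (-log(1 - theta)) and the mean
# theta / ((1 - theta) * (-log(1 - theta))) are closed forms of theta, which
# is what lets tissue presets be calibrated exactly to reported singleton
# fractions.

#' Logarithmic-series probability mass function
#'
#' @param k Positive integer count(s).
#' @param theta Series parameter in (0, 1).
#' @return `P(K = k)` for the log-series distribution.
#' @export
logseries_pmf <- function(k, theta) {
  check_theta(theta)
  stopifnot(all(k >= 1), all(k == floor(k)))
  theta^k / (k * (-log1p(-theta)))
}

#' Expected singleton fraction of the log-series distribution
#'
#' @inheritParams logseries_pmf
#' @return `p_1 = theta / (-log(1 - theta))`.
#' @export
logseries_singleton_fraction <- function(theta) {
  check_theta(theta)
  theta / (-log1p(-theta))
}

#' Mean of the log-series distribution
#'
#' @inheritParams logseries_pmf
#' @return `theta / ((1 - theta) * (-log(1 - theta)))`.
#' @export
logseries_mean <- function(theta) {
  check_theta(theta)
  theta / ((1 - theta) * (-log1p(-theta)))
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta <= 0 || theta >= 1) {
    stop("theta must be a single number in (0, 1)")
  }
  invisible(theta)
}

#' Sample clone sizes from the logarithmic-series distribution
#'
#' Draws i.i.d. clone sizes by inverse-CDF lookup: the cumulative
#' distribution is tabulated until its tail mass falls below `1e-12` and
#' uniform draws are mapped through it. Uses R's global random number
#' generator; call [set.seed()] for reproducibility.
#'
#' @param theta Series parameter in (0, 1); larger values give heavier
#'   clone-size tails (more clonal expansion).
#' @param n Number of clonotypes to draw sizes for.
#' @return Integer vector of `n` counts, all `>= 1`.
#' @examples
#' set.seed(1)
#' mean(sample_clone_sizes(0.6, 1e4) == 1)  # ~ 0.655
#' @export
sample_clone_sizes <- function(theta, n) {
  check_theta(theta)
  stopifnot(n >= 0)
  if (n == 0L) return(integer(0))
  # tabulate the CDF far enough that the untabulated tail is negligible
  kmax <- 64L
  repeat {
    k <- seq_len(kmax)
    pmf <- theta^k / (k * (-log1p(-theta)))
    cdf <- cumsum(pmf)
    if (1 - cdf[kmax] < 1e-12 || kmax > 1e6) break
    kmax <- kmax * 4L
  }
  u <- runif(n)
  counts <- findInterval(u, cdf, left.open = FALSE) + 1L
  # draws beyond the tabulated tail (prob < 1e-12) clamp to the last class
  counts[counts > kmax] <- kmax
  as.integer(counts)
}
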