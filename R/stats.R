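# Repertoire statistics: gene usage, V-J pairing, clone-size structure,
# clonality curves and rare-vs-abundant usage contrasts.
#
# Two weightings recur: "count" weights each clonotype by its abundance
# (what figure legends about "sequences" mean) and "clonotype" treats each
# distinct clonotype equally (what clone-size class fractions are over).

check_clonotypes <- function(clonotypes) {
  stopifnot(is.data.frame(clonotypes))
  if (nrow(clonotypes) == 0L) stop("empty repertoire")
  stopifnot(all(c("v_call", "count") %in% names(clonotypes)))
  invisible(clonotypes)
}

#' V gene usage frequencies
#'
#' @param clonotypes Clonotype data frame from [assemble_clonotypes()].
#' @param weighting `"count"`: frequency of sequences carrying each gene
#'   (weighted by clonotype counts); `"clonotype"`: unweighted over distinct
#'   clonotypes.
#' @param gene Column holding the gene call (default `"v_call"`; use
#'   `"j_call"` for J usage).
#' @return Named numeric vector of frequencies summing to 1, sorted by gene
#'   name.
#' @export
v_usage <- function(clonotypes, weighting = c("count", "clonotype"),
                    gene = "v_call") {
  weighting <- match.arg(weighting)
  check_clonotypes(clonotypes)
  w <- if (weighting == "count") clonotypes$count else
    rep(1, nrow(clonotypes))
  tot <- tapply(w, clonotypes[[gene]], sum)
  out <- as.vector(tot) / sum(w)
  names(out) <- names(tot)
  out[order(names(out))]
}

#' J gene usage frequencies
#'
#' Convenience wrapper around [v_usage()] for the J gene column.
#' @inheritParams v_usage
#' @return Named numeric vector of frequencies summing to 1.
#' @export
j_usage <- function(clonotypes, weighting = c("count", "clonotype")) {
  v_usage(clonotypes, weighting, gene = "j_call")
}

#' V-J pairing percentage matrix
#'
#' Count-weighted percentage of sequences with each (V, J) pairing, over
#' all sequences of the repertoire; entries sum to 100. The row margin
#' equals 100 times the count-weighted V usage.
#'
#' @inheritParams v_usage
#' @return Numeric matrix (V genes as rows, J genes as columns) of
#'   percentages.
#' @export
vj_pairing <- function(clonotypes) {
  check_clonotypes(clonotypes)
  stopifnot("j_call" %in% names(clonotypes))
  tab <- tapply(clonotypes$count,
                list(clonotypes$v_call, clonotypes$j_call), sum,
                default = 0L)
  m <- 100 * tab / sum(clonotypes$count)
  m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}

#' Clone-size class frequencies
#'
#' Fraction of distinct clonotypes observed once, twice, 3, 4 or 5+ times.
#' The class-1 value is the singleton fraction; low singleton fractions
#' indicate clonal expansion.
#'
#' @inheritParams v_usage
#' @return Named numeric vector `c("1","2","3","4","5+")` summing to 1.
#' @export
clone_size_classes <- function(clonotypes) {
  check_clonotypes(clonotypes)
  cnt <- clonotypes$count
  cls <- ifelse(cnt >= 5L, "5+", as.character(cnt))
  out <- setNames(numeric(5), c("1", "2", "3", "4", "5+"))
  tab <- table(cls) / length(cls)
  out[names(tab)] <- as.vector(tab)
  out
}

#' Median clonotype count
#'
#' @inheritParams v_usage
#' @return Median of clonotype counts (mean of the two central order
#'   statistics for even n).
#' @export
median_count <- function(clonotypes) {
  check_clonotypes(clonotypes)
  median(clonotypes$count)
}

#' Cumulative frequency of the top-N clonotypes
#'
#' Sorts clonotypes by count descending (ties broken by amino-acid then
#' nucleotide CDR3, so the ranking is reproducible) and returns the share
#' of all sequences occupied by the `n` most prevalent clonotypes.
#'
#' @inheritParams v_usage
#' @param n Number of top clonotypes (default 25).
#' @return Cumulative frequency in (0, 1]; 1 when the repertoire has `n`
#'   clonotypes or fewer.
#' @export
top_n_cumulative <- function(clonotypes, n = 25L) {
  check_clonotypes(clonotypes)
  if (n < 1L) stop("n must be >= 1")
  aa <- if ("cdr3_aa" %in% names(clonotypes)) clonotypes$cdr3_aa else ""
  nt <- if ("cdr3_nt" %in% names(clonotypes)) clonotypes$cdr3_nt else ""
  ord <- order(-clonotypes$count, aa, nt)
  cnt <- clonotypes$count[ord]
  sum(cnt[seq_len(min(n, length(cnt)))]) / sum(cnt)
}

#' V usage among rare versus abundant clonotypes
#'
#' Contrasts the (unweighted) V gene usage of singleton clonotypes
#' (count = 1) with that of clonotypes at or above an abundance threshold.
#'
#' @inheritParams v_usage
#' @param threshold Minimum count of the abundant stratum (default 2,
#'   i.e. two copies or more).
#' @return List with frequency vectors `rare` and `abundant`; an empty
#'   stratum yields an empty vector with a warning.
#' @export
rare_vs_abundant_usage <- function(clonotypes, threshold = 2L) {
  check_clonotypes(clonotypes)
  if (threshold < 2L) stop("threshold must be >= 2")
  strata <- list(rare = clonotypes[clonotypes$count == 1L, , drop = FALSE],
                 abundant = clonotypes[clonotypes$count >= threshold, ,
                                       drop = FALSE])
  lapply_named <- function(nm) {
    s <- strata[[nm]]
    if (nrow(s) == 0L) {
      warning("empty ", nm, " stratum")
      return(setNames(numeric(0), character(0)))
    }
    v_usage(s, weighting = "clonotype")
  }
  list(rare = lapply_named("rare"), abundant = lapply_named("abundant"))
}

#' Summarise a repertoire
#'
#' Bundles the per-repertoire statistics: V and J usage, V-J pairing,
#' clone-size classes, singleton fraction, median count, cumulative top-N
#' clonality curve and rare-vs-abundant V usage.
#'
#' @inheritParams v_usage
#' @param top_n N for the clonality curve (default 25).
#' @param abundant_threshold Threshold for [rare_vs_abundant_usage()].
#' @param label Scope label recorded in the summary (e.g. tissue name).
#' @return A `repertoire_summary` object.
#' @export
summarize_repertoire <- function(clonotypes, top_n = 25L,
                                 abundant_threshold = 2L, label = NULL) {
  check_clonotypes(clonotypes)
  if (is.null(label)) {
    label <- if ("tissue" %in% names(clonotypes))
      paste(unique(clonotypes$tissue), collapse = "+") else ""
  }
  size_classes <- clone_size_classes(clonotypes)
  ns <- seq_len(min(top_n, nrow(clonotypes)))
  structure(list(
    label = label,
    n_clonotypes = nrow(clonotypes),
    total_count = sum(clonotypes$count),
    v_usage = v_usage(clonotypes, "count"),
    v_usage_by_clonotype = v_usage(clonotypes, "clonotype"),
    j_usage = j_usage(clonotypes, "count"),
    vj_pairing = vj_pairing(clonotypes),
    size_classes = size_classes,
    singleton_fraction = unname(size_classes["1"]),
    median_count = median_count(clonotypes),
    top_n_cumulative = setNames(
      vapply(ns, function(k) top_n_cumulative(clonotypes, k), 0), ns),
    rare_vs_abundant = suppressWarnings(
      rare_vs_abundant_usage(clonotypes, abundant_threshold)),
    abundant_threshold = abundant_threshold
  ), class = "repertoire_summary")
}

#' @export
print.repertoire_summary <- function(x, ...) {
  cat("Repertoire summary", if (nzchar(x$label)) paste0("[", x$label, "]"),
      "\n")
  cat("  clonotypes:", x$n_clonotypes, " sequences:", x$total_count, "\n")
  cat("  singleton fraction:", round(x$singleton_fraction, 4),
      " median count:", x$median_count, "\n")
  top <- x$top_n_cumulative[length(x$top_n_cumulative)]
  cat("  top-", names(top), " cumulative frequency: ",
      round(unname(top), 4), "\n", sep = "")
  cat("  V usage (by count):\n")
  print(round(x$v_usage, 4))
  invisible(x)
}

#' @export
plot.repertoire_summary <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::barplot(x$v_usage, las = 2, ylab = "frequency",
                    main = paste("V usage", x$label))
  graphics::barplot(x$size_classes, ylab = "fraction of clonotypes",
                    xlab = "clone size", main = "Clone-size classes")
  invisible(x)
}
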