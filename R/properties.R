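# CDR3 physicochemical profiling: Kyte-Doolittle hydrophobicity,
# EMBOSS-style isoelectric point, residue-class composition, length spectra
# and position frequency matrices with per-column information content.
#
# Ambiguous residues (X) contribute zero hydropathy and no charge, and are
# excluded from class-frequency denominators; a warning is emitted.

split_aa <- function(x, allow_x = TRUE) {
  chars <- strsplit(x, "")[[1]]
  extra <- if (allow_x) "X" else character(0)
  bad <- setdiff(chars, c(AA_STANDARD, extra))
  if (length(bad) > 0L) {
    stop("invalid amino-acid character(s): ", paste(unique(bad),
                                                    collapse = ", "))
  }
  if (allow_x && any(chars == "X")) {
    warning("ambiguous residue X treated as neutral")
  }
  chars
}

#' Mean Kyte-Doolittle hydrophobicity of a peptide
#'
#' Arithmetic mean (or sum) of per-residue hydropathy values. Ambiguous
#' residues (X) contribute 0 but stay in the denominator, so the mean of a
#' concatenation is the length-weighted mean of its parts.
#'
#' @param x Character vector of amino-acid sequences.
#' @param scale Named hydropathy scale (default [KD_SCALE]).
#' @param method `"mean"` (default, scale-free across lengths) or `"sum"`.
#' @return Numeric vector of hydrophobicity values.
#' @examples
#' hydrophobicity("CASSF")  # 1.1
#' @export
hydrophobicity <- function(x, scale = KD_SCALE, method = c("mean", "sum")) {
  method <- match.arg(method)
  stopifnot(all(AA_STANDARD %in% names(scale)), all(is.finite(scale)))
  vapply(x, function(s) {
    if (is.na(s) || nchar(s) == 0L) stop("empty sequence")
    chars <- split_aa(s)
    vals <- ifelse(chars == "X", 0, scale[chars])
    if (method == "mean") mean(vals) else sum(vals)
  }, numeric(1), USE.NAMES = FALSE)
}

# net charge of a peptide at given pH values, from per-group counts;
# strictly decreasing in pH
peptide_charge <- function(counts, pH, pk) {
  pos <- c("Nterm", "K", "R", "H")
  neg <- c("Cterm", "D", "E", "C", "Y")
  q <- 0
  for (g in pos) q <- q + counts[[g]] / (1 + 10^(pH - pk[[g]]))
  for (g in neg) q <- q - counts[[g]] / (1 + 10^(pk[[g]] - pH))
  q
}

ionizable_counts <- function(chars) {
  list(Nterm = 1, Cterm = 1,
       K = sum(chars == "K"), R = sum(chars == "R"), H = sum(chars == "H"),
       D = sum(chars == "D"), E = sum(chars == "E"), C = sum(chars == "C"),
       Y = sum(chars == "Y"))
}

#' Isoelectric point of a peptide
#'
#' pH at which the net charge is zero, from the Henderson-Hasselbalch
#' charge balance with the EMBOSS default pK set (both termini treated as
#' ionizable, free cysteines). The charge is strictly decreasing in pH, so
#' the root on the interval 0-14 is unique; it is found by bisection, stopped when
#' the absolute charge falls below `tol`.
#'
#' @param x Character vector of amino-acid sequences.
#' @param pk Named pK table (default [EMBOSS_PK]).
#' @param tol Charge tolerance of the bisection (default 1e-4).
#' @return Numeric vector of pI values between 0 and 14.
#' @examples
#' isoelectric_point("GGG")  # 6.1, the midpoint of the two terminal pKs
#' @export
isoelectric_point <- function(x, pk = EMBOSS_PK, tol = 1e-4) {
  needed <- c("Nterm", "Cterm", "K", "R", "H", "D", "E", "C", "Y")
  stopifnot(all(needed %in% names(pk)), all(pk > 0 & pk < 14))
  vapply(x, function(s) {
    if (is.na(s) || nchar(s) == 0L) stop("empty sequence")
    counts <- ionizable_counts(split_aa(s))
    lo <- 0; hi <- 14
    q_lo <- peptide_charge(counts, lo, pk)
    q_hi <- peptide_charge(counts, hi, pk)
    if (q_lo < 0 || q_hi > 0) {
      warning("no sign change on [0, 14]; returning boundary")
      return(if (q_lo < 0) lo else hi)
    }
    # bisect to interval convergence: near-flat charge curves make the
    # |Q| < tol region much wider than the root's neighbourhood, so the
    # charge criterion alone cannot localise the pI
    while (hi - lo > 1e-8) {
      mid <- (lo + hi) / 2
      if (peptide_charge(counts, mid, pk) > 0) lo <- mid else hi <- mid
    }
    mid <- (lo + hi) / 2
    if (abs(peptide_charge(counts, mid, pk)) >= tol) {
      warning("bisection converged with |charge| >= tol")
    }
    mid
  }, numeric(1), USE.NAMES = FALSE)
}

#' Residue-class composition of peptides
#'
#' Fraction of polar, aliphatic and aromatic residues per sequence.
#' Histidine counts toward both the polar and the aromatic class, so the
#' three fractions may sum above 1. Ambiguous residues (X) are excluded
#' from the denominator.
#'
#' @param x Character vector of amino-acid sequences.
#' @param classes Residue class definition (default [RESIDUE_CLASSES]).
#' @return Data frame with columns `polar`, `aliphatic`, `aromatic`, one
#'   row per sequence.
#' @export
residue_class_freqs <- function(x, classes = RESIDUE_CLASSES) {
  rows <- lapply(x, function(s) {
    if (is.na(s) || nchar(s) == 0L) stop("empty sequence")
    chars <- split_aa(s)
    chars <- chars[chars != "X"]
    denom <- length(chars)
    vapply(classes, function(cl)
      if (denom == 0L) 0 else sum(chars %in% cl) / denom, numeric(1))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- names(classes)
  out
}

#' Amino-acid length distribution
#'
#' @param x Character vector of amino-acid sequences.
#' @return List with `freq` (named frequency vector over observed lengths,
#'   summing to 1) and `mode` (smallest length achieving the maximum
#'   frequency).
#' @export
length_distribution <- function(x) {
  if (length(x) == 0L) stop("empty sequence set")
  lens <- nchar(x)
  tab <- table(lens) / length(lens)
  freq <- setNames(as.vector(tab), names(tab))
  mode <- min(as.integer(names(freq)[freq == max(freq)]))
  list(freq = freq, mode = mode)
}

#' Position frequency matrix and information content
#'
#' Filters sequences to exactly `fixed_length` amino acids (reporting how
#' many were kept) and computes the 20-row position frequency matrix plus
#' per-column information content `IC = log2(20) - H` in bits, with H the
#' Shannon entropy of the column. No small-sample correction is applied;
#' the kept-sequence count is reported so such a correction is
#' recomputable.
#'
#' @param x Character vector of amino-acid sequences.
#' @param fixed_length Length (aa) the logo is computed at.
#' @return A `cdr3_pfm` object: list with `pfm` (20 x `fixed_length`
#'   column-stochastic matrix), `ic` (per-position bits), `consensus`,
#'   `n_kept` and `n_total`.
#' @export
position_frequency_matrix <- function(x, fixed_length) {
  if (length(x) == 0L) stop("empty sequence set")
  keep <- nchar(x) == fixed_length & !grepl("[^A-Z]", x)
  kept <- x[keep]
  if (length(kept) == 0L) {
    stop("no sequence of length ", fixed_length, " aa")
  }
  mat <- do.call(rbind, strsplit(kept, ""))
  bad <- !(mat %in% AA_STANDARD)
  if (any(bad)) {
    warning(sum(bad), " non-standard residue(s) ignored in PFM counts")
  }
  pfm <- vapply(seq_len(fixed_length), function(j) {
    col <- mat[, j]
    col <- col[col %in% AA_STANDARD]
    tab <- table(factor(col, levels = AA_STANDARD))
    as.vector(tab) / length(col)
  }, numeric(length(AA_STANDARD)))
  rownames(pfm) <- AA_STANDARD
  colnames(pfm) <- seq_len(fixed_length)
  ic <- apply(pfm, 2, function(p) {
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  })
  consensus <- paste(rownames(pfm)[apply(pfm, 2, which.max)], collapse = "")
  structure(list(pfm = pfm, ic = ic, consensus = consensus,
                 n_kept = length(kept), n_total = length(x),
                 fixed_length = fixed_length),
            class = "cdr3_pfm")
}

#' @export
print.cdr3_pfm <- function(x, ...) {
  cat("CDR3 position frequency matrix (", x$fixed_length, " aa; ",
      x$n_kept, "/", x$n_total, " sequences kept)\n", sep = "")
  cat("  consensus:", x$consensus, "\n")
  cat("  information content (bits):",
      paste(round(x$ic, 2), collapse = " "), "\n")
  invisible(x)
}

#' Per-sequence CDR3 property table
#'
#' Convenience wrapper computing length, hydrophobicity, isoelectric point
#' and residue-class fractions for each sequence.
#'
#' @param x Character vector of amino-acid sequences.
#' @return Data frame with one row per sequence.
#' @export
cdr3_properties <- function(x) {
  if (length(x) == 0L) stop("empty sequence set")
  cbind(
    data.frame(cdr3_aa = x, length = nchar(x),
               hydrophobicity = hydrophobicity(x),
               pI = isoelectric_point(x), stringsAsFactors = FALSE),
    residue_class_freqs(x)
  )
}
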