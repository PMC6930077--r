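# Tissue presets for the synthetic repertoire generator.
#
# Clone sizes follow a logarithmic-series distribution whose parameter theta
# is calibrated so that the expected singleton fraction
# p1 = theta / (-log(1 - theta)) matches the singleton fractions reported
# for each tissue (~65% spleen/thymus, ~50% mesenteric LN, ~40% inguinal
# LN). TRBV vectors reproduce the qualitative ordering seen across tissues
# (TRBV13-2 depressed and "other" V genes elevated in lymph nodes); they are
# configuration, not ground truth. TRBJ usage is uniform by default because
# no quantitative per-tissue TRBJ table is available.

TISSUE_NAMES <- c("thymus", "spleen", "mLN", "iLN")

PRESET_THETA <- c(thymus = 0.60, spleen = 0.60, mLN = 0.80, iLN = 0.90)

PRESET_TRBV <- list(
  spleen = c("TRBV1" = 0.05, "TRBV13-1" = 0.12, "TRBV13-2" = 0.35,
             "TRBV13-3" = 0.05, "TRBV19" = 0.08, "TRBV29" = 0.25,
             "TRBVother" = 0.10),
  thymus = c("TRBV1" = 0.04, "TRBV13-1" = 0.12, "TRBV13-2" = 0.38,
             "TRBV13-3" = 0.05, "TRBV19" = 0.07, "TRBV29" = 0.24,
             "TRBVother" = 0.10),
  mLN    = c("TRBV1" = 0.08, "TRBV13-1" = 0.10, "TRBV13-2" = 0.25,
             "TRBV13-3" = 0.05, "TRBV19" = 0.10, "TRBV29" = 0.27,
             "TRBVother" = 0.15),
  iLN    = c("TRBV1" = 0.10, "TRBV13-1" = 0.10, "TRBV13-2" = 0.20,
             "TRBV13-3" = 0.05, "TRBV19" = 0.10, "TRBV29" = 0.25,
             "TRBVother" = 0.20)
)

DEFAULT_CDR3B_LENGTH_PROBS <- c(
  "11" = 0.03, "12" = 0.09, "13" = 0.18, "14" = 0.30,
  "15" = 0.20, "16" = 0.12, "17" = 0.06, "18" = 0.02
)

#' Tissue preset for the repertoire generator
#'
#' Bundles the generator parameters for one tissue: TRBV/TRBJ usage
#' probability vectors, the log-series clone-size parameter `theta`, the
#' fraction of alpha clonotypes carrying the canonical TRAV11-TRAJ18
#' rearrangement, the CDR3beta amino-acid length spectrum (mode 14 aa) and
#' the fraction of beta clonotypes generated as nonproductive
#' rearrangements.
#'
#' @param name One of `"thymus"`, `"spleen"`, `"mLN"`, `"iLN"`.
#' @param ... Named overrides for any preset field (`trbv_probs`,
#'   `trbj_probs`, `theta`, `canonical_alpha_fraction`,
#'   `cdr3b_length_probs`, `nonproductive_rate`).
#' @return A `tissue_preset` object (a validated list).
#' @examples
#' p <- tissue_preset("spleen")
#' p$theta
#' logseries_singleton_fraction(p$theta)  # expected singleton fraction
#' @export
tissue_preset <- function(name = c("thymus", "spleen", "mLN", "iLN"), ...) {
  name <- match.arg(name)
  preset <- list(
    name = name,
    trbv_probs = PRESET_TRBV[[name]],
    trbj_probs = c("TRBJ1-1" = 1, "TRBJ2-1" = 1, "TRBJ2-7" = 1) / 3,
    theta = PRESET_THETA[[name]],
    canonical_alpha_fraction = 0.97,
    cdr3b_length_probs = DEFAULT_CDR3B_LENGTH_PROBS,
    nonproductive_rate = 0.10
  )
  overrides <- list(...)
  if (length(overrides) > 0L) {
    bad <- setdiff(names(overrides), names(preset))
    if (length(bad) > 0L || is.null(names(overrides))) {
      stop("unknown preset field(s): ", paste(bad, collapse = ", "))
    }
    preset[names(overrides)] <- overrides
  }
  validate_preset(preset)
  structure(preset, class = "tissue_preset")
}

validate_preset <- function(p) {
  for (field in c("trbv_probs", "trbj_probs", "cdr3b_length_probs")) {
    v <- p[[field]]
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      stop("preset field ", field, " must be a probability vector summing to 1")
    }
  }
  if (!(p$theta > 0 && p$theta < 1)) stop("theta must lie in (0, 1)")
  for (field in c("canonical_alpha_fraction", "nonproductive_rate")) {
    if (p[[field]] < 0 || p[[field]] > 1) {
      stop(field, " must lie in [0, 1]")
    }
  }
  invisible(p)
}

#' @export
print.tissue_preset <- function(x, ...) {
  cat("Tissue preset:", x$name, "\n")
  cat("  theta =", x$theta,
      "(expected singleton fraction",
      round(logseries_singleton_fraction(x$theta), 4), ")\n")
  cat("  canonical alpha fraction =", x$canonical_alpha_fraction, "\n")
  cat("  nonproductive rate =", x$nonproductive_rate, "\n")
  cat("  TRBV:", paste(sprintf("%s=%.2f", names(x$trbv_probs), x$trbv_probs),
                       collapse = " "), "\n")
  invisible(x)
}
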