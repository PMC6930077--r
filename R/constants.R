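#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values for the 20 standard amino acids
#' (Kyte & Doolittle 1982). Positive values are hydrophobic.
#'
#' @format Named numeric vector of length 20.
#' @export
KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' EMBOSS default pK values for ionizable groups
#'
#' pK values used for isoelectric-point calculation: the two peptide termini
#' plus the seven ionizable side chains, with the EMBOSS defaults. The
#' N-terminus, K, R and H are treated as basic (positively charged below
#' their pK); the C-terminus, D, E, C and Y as acidic.
#'
#' @format Named numeric vector of length 9 (names `Nterm`, `Cterm`, `K`,
#'   `R`, `H`, `D`, `E`, `C`, `Y`).
#' @export
EMBOSS_PK <- c(
  Nterm = 8.6, Cterm = 3.6,
  K = 10.8, R = 12.5, H = 6.5,
  D = 3.9, E = 4.1, C = 8.5, Y = 10.1
)

#' Residue classes used for CDR3 composition profiling
#'
#' Polar, aliphatic and aromatic residue sets. Histidine belongs to both the
#' polar and the aromatic class, so class fractions of a sequence may sum to
#' more than 1.
#'
#' @format Named list of three character vectors.
#' @export
RESIDUE_CLASSES <- list(
  polar     = c("D", "E", "H", "K", "N", "Q", "R", "S", "T"),
  aliphatic = c("A", "I", "L", "V"),
  aromatic  = c("F", "H", "W", "Y")
)

# the 20 standard amino-acid one-letter codes
AA_STANDARD <- names(KD_SCALE)

# stop codons of the standard genetic code
STOP_CODONS <- c("TAA", "TAG", "TGA")
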