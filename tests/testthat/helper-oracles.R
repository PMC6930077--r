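# Independent oracles, coded without reference to the package internals.

# hand-coded standard genetic code, indexed by codon
ORACLE_CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

oracle_translate <- function(nt) {
  vapply(nt, function(s) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste(ORACLE_CODON_TABLE[codons], collapse = "")
  }, "", USE.NAMES = FALSE)
}

# grid search for the isoelectric point at 1e-4 pH resolution; the charge
# is strictly decreasing in pH, so a coarse pass plus a fine pass around the
# sign change is equivalent to scanning the full 0-14 grid
oracle_pi_grid <- function(seq, pk = repsim::EMBOSS_PK) {
  chars <- strsplit(seq, "")[[1]]
  n <- c(Nterm = 1, Cterm = 1, K = sum(chars == "K"), R = sum(chars == "R"),
         H = sum(chars == "H"), D = sum(chars == "D"), E = sum(chars == "E"),
         C = sum(chars == "C"), Y = sum(chars == "Y"))
  Q <- function(pH) {
    n[["Nterm"]] / (1 + 10^(pH - pk[["Nterm"]])) +
      n[["K"]] / (1 + 10^(pH - pk[["K"]])) +
      n[["R"]] / (1 + 10^(pH - pk[["R"]])) +
      n[["H"]] / (1 + 10^(pH - pk[["H"]])) -
      n[["Cterm"]] / (1 + 10^(pk[["Cterm"]] - pH)) -
      n[["D"]] / (1 + 10^(pk[["D"]] - pH)) -
      n[["E"]] / (1 + 10^(pk[["E"]] - pH)) -
      n[["C"]] / (1 + 10^(pk[["C"]] - pH)) -
      n[["Y"]] / (1 + 10^(pk[["Y"]] - pH))
  }
  coarse <- seq(0, 14, by = 0.01)
  qc <- Q(coarse)
  i <- max(which(qc > 0))
  fine <- seq(max(0, coarse[i] - 0.01), min(14, coarse[i] + 0.01), by = 1e-4)
  fine[which.min(abs(Q(fine)))]
}

# exact Mann-Whitney oracle: direct pairwise-comparison U over every
# assignment of the pooled values to the two groups
oracle_mw_exact <- function(a, b) {
  u_of <- function(x, y) {
    s <- 0
    for (xi in x) for (yi in y) s <- s + (xi > yi) + 0.5 * (xi == yi)
    s
  }
  pooled <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pooled), na)
  u_all <- apply(idx, 2, function(sel)
    u_of(pooled[sel], pooled[-sel]))
  u_obs <- u_of(a, b)
  eps <- 1e-9
  list(U = u_obs,
       p = min(1, 2 * min(mean(u_all <= u_obs + eps),
                          mean(u_all >= u_obs - eps))))
}

# brute-force rejection sampler for the log-series distribution: geometric
# proposal q_k = (1-theta) theta^(k-1), acceptance probability 1/k
oracle_logseries_rejection <- function(theta, n) {
  out <- integer(0)
  while (length(out) < n) {
    k <- 1L + stats::rgeom(2L * n, prob = 1 - theta)
    keep <- stats::runif(length(k)) < 1 / k
    out <- c(out, k[keep])
  }
  out[seq_len(n)]
}

random_peptides <- function(n, min_len = 5, max_len = 20) {
  aa <- names(repsim::KD_SCALE)
  vapply(seq_len(n), function(i) {
    paste(sample(aa, sample(min_len:max_len, 1), replace = TRUE),
          collapse = "")
  }, "")
}
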