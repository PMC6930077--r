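# Large simulated repertoires are shared across test files.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(tissue, n = 20000L, seed = 42L) {
  key <- paste(tissue, n, seed, sep = "_")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_repertoire(tissue_preset(tissue), n,
                                             seed = seed)
  }
  .sim_cache[[key]]
}

# pooled productive beta-chain clonotypes of a cached repertoire
cached_clonotypes <- function(tissue, n = 20000L, seed = 42L) {
  key <- paste("cl", tissue, n, seed, sep = "_")
  if (is.null(.sim_cache[[key]])) {
    rec <- cached_sim(tissue, n, seed)$rearrangements
    trb <- rec[rec$locus == "TRB", , drop = FALSE]
    .sim_cache[[key]] <- suppressMessages(
      assemble_clonotypes(trb, scope = "pooled"))
  }
  .sim_cache[[key]]
}

random_airr_records <- function(n) {
  bases <- c("A", "C", "G", "T")
  junction <- vapply(seq_len(n), function(i)
    paste(sample(bases, 3 * sample(4:6, 1), replace = TRUE), collapse = ""),
    "")
  cls <- classify_productive(junction)
  data.frame(
    sequence_id = sprintf("r%04d", seq_len(n)),
    sequence = paste0("AAA", junction, "GGG"),
    v_call = sample(c("TRBV1", "TRBV29", "TRBV13-2"), n, replace = TRUE),
    d_call = "",
    j_call = sample(c("TRBJ1-1", "TRBJ2-7"), n, replace = TRUE),
    junction = junction,
    junction_aa = cls$junction_aa,
    productive = cls$productive,
    duplicate_count = sample(1:9, n, replace = TRUE),
    locus = "TRB",
    sample_id = sample(c("s1", "s2"), n, replace = TRUE),
    tissue = sample(c("spleen", "iLN"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
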