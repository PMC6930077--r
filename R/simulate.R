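# Synthetic repertoire generator.
#
# Each clonotype gets a TRBV/TRBJ pair drawn from the preset usage vectors,
# a clone size from the log-series model, and a CDR3beta junction built from
# germline-templated ends (V cysteine codon onward, J start through the
# phenylalanine codon) joined by an untemplated N region. A parallel TRA
# record is emitted per clonotype; a preset-controlled share carries the
# canonical TRAV11-TRAJ18 rearrangement with a fixed conserved CDR3alpha.
# A preset-controlled share of beta clonotypes is generated nonproductive
# (frameshifted or with an in-frame stop) to exercise downstream filtering.

NONSTOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
})

# fixed reverse-translation map used for the canonical CDR3alpha middle
AA_TO_CODON <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAC", I = "ATT", K = "AAA", L = "CTT", M = "ATG", N = "AAT",
  P = "CCT", Q = "CAA", R = "CGT", S = "AGT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT"
)

#' Default canonical CDR3alpha junction sequence
#'
#' The 15-aa conserved CDR3alpha junction used for the canonical
#' TRAV11-TRAJ18 rearrangement, the widely reported canonical mouse iNKT
#' alpha junction. Starts at the conserved cysteine and ends at the
#' conserved phenylalanine.
#' @format Character scalar.
#' @export
CANONICAL_CDR3A <- "CVVGDRGSALGRLHF"

#' Generate one CDR3 junction from germline-templated ends
#'
#' Builds a junction as V-templated prefix (from the conserved Cys codon to
#' the V segment end) + untemplated N region + J-templated suffix (J start
#' through the conserved Phe/Trp codon). Productive junctions have length
#' `3 * target_aa_length`, translate without stops, and start with the V
#' cysteine. When `force_nonproductive = TRUE` the junction is either
#' frameshifted (length not a multiple of 3) or carries an in-frame stop
#' codon, with the choice made at random.
#'
#' @param v,j Single rows of the `v_segments` / `j_segments` tables of a
#'   [read_germline()] reference (or the gene name, resolved against
#'   `germline`).
#' @param target_aa_length Desired junction length in amino acids.
#' @param force_nonproductive Generate a nonproductive junction instead.
#' @param germline Germline reference used to resolve gene names.
#' @return List with `junction` (nt), `junction_aa` (empty when
#'   nonproductive) and `productive`.
#' @export
generate_cdr3_nt <- function(v, j, target_aa_length,
                             force_nonproductive = FALSE,
                             germline = NULL) {
  if (is.character(v)) v <- germline_v(germline, v)
  if (is.character(j)) j <- germline_j(germline, j)
  v_part <- substr(v$sequence, v$cys_anchor + 1L, nchar(v$sequence))
  j_part <- substr(j$sequence, 1L, j$phe_anchor + 3L)
  n_len <- 3L * target_aa_length - nchar(v_part) - nchar(j_part)
  if (n_len < 0L) {
    stop("impossible junction length ", target_aa_length,
         " aa given anchor geometry of ", v$gene, "/", j$gene)
  }
  codon_aligned <- nchar(v_part) %% 3L == 0L && n_len %% 3L == 0L
  if (!force_nonproductive) {
    junction <- paste0(v_part, sample_nonstop_region(n_len, codon_aligned),
                       j_part)
    aa <- translate_nt(junction)
    if (grepl("\\*", aa, fixed = FALSE)) {
      # templated parts can only carry stops with a non-toy reference;
      # resample the whole junction a bounded number of times
      for (i in seq_len(1000L)) {
        junction <- paste0(v_part, sample_nonstop_region(n_len, codon_aligned),
                           j_part)
        aa <- translate_nt(junction)
        if (!grepl("*", aa, fixed = TRUE)) break
      }
      if (grepl("*", aa, fixed = TRUE)) {
        stop("could not generate a stop-free junction for ", v$gene, "/",
             j$gene, " at length ", target_aa_length)
      }
    }
    list(junction = junction, junction_aa = aa, productive = TRUE)
  } else {
    mode <- if (n_len >= 3L && runif(1) < 0.5) "stop" else "frameshift"
    if (mode == "frameshift") {
      shift <- sample(c(-1L, 1L), 1L)
      if (n_len + shift < 0L) shift <- 1L
      middle <- paste(sample(c("A", "C", "G", "T"), n_len + shift,
                             replace = TRUE), collapse = "")
      junction <- paste0(v_part, middle, j_part)
    } else {
      middle_codons <- sample(NONSTOP_CODONS, n_len %/% 3L, replace = TRUE)
      middle_codons[sample.int(length(middle_codons), 1L)] <-
        sample(STOP_CODONS, 1L)
      junction <- paste0(v_part, paste(middle_codons, collapse = ""), j_part)
    }
    list(junction = junction, junction_aa = "", productive = FALSE)
  }
}

# vectorised clean-junction construction for codon-aligned references;
# falls back to NULL when the geometry is not codon-aligned so the caller
# can use the scalar generator instead
batch_clean_junctions <- function(germline, v_genes, j_genes, lens) {
  vi <- match(v_genes, germline$v_segments$gene)
  ji <- match(j_genes, germline$j_segments$gene)
  v_seq <- germline$v_segments$sequence[vi]
  v_part <- substr(v_seq, germline$v_segments$cys_anchor[vi] + 1L,
                   nchar(v_seq))
  j_part <- substr(germline$j_segments$sequence[ji], 1L,
                   germline$j_segments$phe_anchor[ji] + 3L)
  n_len <- 3L * lens - nchar(v_part) - nchar(j_part)
  if (any(n_len < 0L)) {
    stop("impossible junction length given anchor geometry")
  }
  if (any(nchar(v_part) %% 3L != 0L) || any(n_len %% 3L != 0L)) {
    return(NULL)
  }
  k <- n_len %/% 3L
  middles <- character(length(k))
  if (sum(k) > 0L) {
    cods <- sample(NONSTOP_CODONS, sum(k), replace = TRUE)
    grp <- factor(rep.int(seq_along(k), k), levels = seq_along(k))
    middles <- vapply(split(cods, grp), paste, "", collapse = "",
                      USE.NAMES = FALSE)
  }
  paste0(v_part, middles, j_part)
}

sample_nonstop_region <- function(n_len, codon_aligned) {
  if (n_len == 0L) return("")
  if (codon_aligned) {
    paste(sample(NONSTOP_CODONS, n_len %/% 3L, replace = TRUE), collapse = "")
  } else {
    paste(sample(c("A", "C", "G", "T"), n_len, replace = TRUE), collapse = "")
  }
}

#' Simulate a tissue-specific iNKT repertoire
#'
#' Generates `n_clonotypes` paired TRA/TRB rearrangement records with the
#' statistical structure of the given tissue preset: TRBV/TRBJ usage, a
#' log-series clone-size distribution, a CDR3beta length spectrum with mode
#' 14 aa, a near-invariant alpha chain (a `canonical_alpha_fraction` share
#' of alpha records carries the canonical TRAV11-TRAJ18 rearrangement with
#' the conserved 15-aa CDR3alpha), and a `nonproductive_rate` share of
#' frameshifted or stop-containing beta rearrangements. Output is
#' deterministic given `seed`.
#'
#' @param preset A [tissue_preset()] object or a tissue name.
#' @param n_clonotypes Number of clonotypes to generate.
#' @param seed Integer seed; the single source of randomness for the run.
#' @param germline Germline reference; defaults to the shipped synthetic toy
#'   reference.
#' @param samples_per_tissue Number of biological samples the clonotypes are
#'   distributed over (default 4, matching the per-tissue replication of the
#'   study design the generator emulates).
#' @param canonical_cdr3a Canonical CDR3alpha amino-acid junction; must be
#'   compatible with the TRAV11/TRAJ18 templated ends of the reference.
#' @return A `sim_repertoire` object: list with `rearrangements` (AIRR-style
#'   data frame, two records per clonotype), `truth` (ground-truth table
#'   with `sequence_id`, `true_v_call`, `true_j_call`, `true_junction`,
#'   `true_productive`), `preset` and `seed`.
#' @examples
#' rep <- simulate_repertoire(tissue_preset("spleen"), 50, seed = 1)
#' head(rep$rearrangements[, c("v_call", "junction_aa", "duplicate_count")])
#' @export
simulate_repertoire <- function(preset, n_clonotypes, seed,
                                germline = toy_germline(),
                                samples_per_tissue = 4L,
                                canonical_cdr3a = CANONICAL_CDR3A) {
  if (is.character(preset)) preset <- tissue_preset(preset)
  stopifnot(inherits(preset, "tissue_preset"), n_clonotypes > 0,
            samples_per_tissue >= 1L)
  seed <- as.integer(seed)
  set.seed(seed)
  n <- as.integer(n_clonotypes)
  tissue <- preset$name

  sizes <- sample_clone_sizes(preset$theta, n)
  v_genes <- sample(names(preset$trbv_probs), n, replace = TRUE,
                    prob = preset$trbv_probs)
  j_genes <- sample(names(preset$trbj_probs), n, replace = TRUE,
                    prob = preset$trbj_probs)
  lens <- sample(as.integer(names(preset$cdr3b_length_probs)), n,
                 replace = TRUE, prob = preset$cdr3b_length_probs)
  nonprod <- runif(n) < preset$nonproductive_rate
  canonical <- runif(n) < preset$canonical_alpha_fraction
  sample_ids <- sprintf("%s_s%d", tissue,
                        sample.int(samples_per_tissue, n, replace = TRUE))

  # beta chain records: clean junctions are built in one vectorised pass
  # (single batch translation); nonproductive ones individually
  b_junction <- character(n)
  b_aa <- character(n)
  b_prod <- !nonprod
  clean <- which(!nonprod)
  if (length(clean) > 0L) {
    jcl <- batch_clean_junctions(germline, v_genes[clean], j_genes[clean],
                                 lens[clean])
    if (is.null(jcl)) {
      for (i in clean) {
        g <- generate_cdr3_nt(v_genes[i], j_genes[i], lens[i],
                              germline = germline)
        b_junction[i] <- g$junction
        b_aa[i] <- g$junction_aa
      }
    } else {
      aa <- translate_nt(jcl)
      stops <- grepl("*", aa, fixed = TRUE)
      for (s in which(stops)) {  # templated stop: regenerate individually
        g <- generate_cdr3_nt(v_genes[clean[s]], j_genes[clean[s]],
                              lens[clean[s]], germline = germline)
        jcl[s] <- g$junction
        aa[s] <- g$junction_aa
      }
      b_junction[clean] <- jcl
      b_aa[clean] <- aa
    }
  }
  for (i in which(nonprod)) {
    g <- generate_cdr3_nt(v_genes[i], j_genes[i], lens[i],
                          force_nonproductive = TRUE, germline = germline)
    b_junction[i] <- g$junction
  }

  # alpha chain records: canonical share is the fixed TRAV11-TRAJ18
  # rearrangement; the rest use an alternative TRAV/TRAJ
  trav <- grep("^TRAV", germline$v_segments$gene, value = TRUE)
  traj <- grep("^TRAJ", germline$j_segments$gene, value = TRUE)
  if (!("TRAV11" %in% trav) || !("TRAJ18" %in% traj)) {
    stop("germline reference must contain TRAV11 and TRAJ18")
  }
  canon_nt <- canonical_alpha_junction(germline, canonical_cdr3a)
  alt_v <- setdiff(trav, "TRAV11")
  alt_j <- setdiff(traj, "TRAJ18")
  a_v <- ifelse(canonical, "TRAV11",
                sample(rep(alt_v, 2L), n, replace = TRUE))
  a_j <- ifelse(canonical, "TRAJ18",
                sample(rep(alt_j, 2L), n, replace = TRUE))
  a_junction <- character(n)
  a_aa <- character(n)
  a_junction[canonical] <- canon_nt
  a_aa[canonical] <- canonical_cdr3a
  noncanon <- which(!canonical)
  if (length(noncanon) > 0L) {
    a_lens <- sample(as.integer(names(preset$cdr3b_length_probs)),
                     length(noncanon), replace = TRUE,
                     prob = preset$cdr3b_length_probs)
    jnc <- batch_clean_junctions(germline, a_v[noncanon], a_j[noncanon],
                                 a_lens)
    if (is.null(jnc)) {
      for (s in seq_along(noncanon)) {
        g <- generate_cdr3_nt(a_v[noncanon[s]], a_j[noncanon[s]], a_lens[s],
                              germline = germline)
        a_junction[noncanon[s]] <- g$junction
        a_aa[noncanon[s]] <- g$junction_aa
      }
    } else {
      aa <- translate_nt(jnc)
      for (s in which(grepl("*", aa, fixed = TRUE))) {
        g <- generate_cdr3_nt(a_v[noncanon[s]], a_j[noncanon[s]], a_lens[s],
                              germline = germline)
        jnc[s] <- g$junction
        aa[s] <- g$junction_aa
      }
      a_junction[noncanon] <- jnc
      a_aa[noncanon] <- aa
    }
  }

  rearr <- rbind(
    build_records(sprintf("c%06d_TRB", seq_len(n)), v_genes, j_genes,
                  b_junction, b_aa, b_prod, sizes, "TRB", sample_ids,
                  tissue, germline),
    build_records(sprintf("c%06d_TRA", seq_len(n)), a_v, a_j,
                  a_junction, a_aa, rep(TRUE, n), sizes, "TRA", sample_ids,
                  tissue, germline)
  )
  truth <- data.frame(
    sequence_id = rearr$sequence_id,
    true_v_call = rearr$v_call,
    true_j_call = rearr$j_call,
    true_junction = rearr$junction,
    true_productive = rearr$productive,
    stringsAsFactors = FALSE
  )
  structure(list(rearrangements = rearr, truth = truth, preset = preset,
                 seed = seed, n_clonotypes = n,
                 samples_per_tissue = as.integer(samples_per_tissue)),
            class = "sim_repertoire")
}

# full-length read = V segment up to the junction start + junction +
# J segment after the junction end
build_records <- function(ids, v_genes, j_genes, junction, junction_aa,
                          productive, counts, locus, sample_ids, tissue,
                          germline) {
  vi <- match(v_genes, germline$v_segments$gene)
  ji <- match(j_genes, germline$j_segments$gene)
  v_head <- substr(germline$v_segments$sequence[vi], 1L,
                   germline$v_segments$cys_anchor[vi])
  j_seq <- germline$j_segments$sequence[ji]
  j_tail <- substr(j_seq, germline$j_segments$phe_anchor[ji] + 4L,
                   nchar(j_seq))
  data.frame(
    sequence_id = ids,
    sequence = paste0(v_head, junction, j_tail),
    v_call = v_genes, d_call = "", j_call = j_genes,
    junction = junction, junction_aa = junction_aa,
    productive = productive,
    duplicate_count = as.integer(counts),
    locus = locus, sample_id = sample_ids, tissue = tissue,
    stringsAsFactors = FALSE
  )
}

# fixed nucleotide encoding of the canonical CDR3alpha: templated V/J ends
# plus a deterministic reverse translation of the middle
canonical_alpha_junction <- function(germline, canonical_cdr3a) {
  v <- germline_v(germline, "TRAV11")
  j <- germline_j(germline, "TRAJ18")
  v_part <- substr(v$sequence, v$cys_anchor + 1L, nchar(v$sequence))
  j_part <- substr(j$sequence, 1L, j$phe_anchor + 3L)
  aa <- strsplit(canonical_cdr3a, "")[[1]]
  n_v <- nchar(v_part) %/% 3L
  n_j <- nchar(j_part) %/% 3L
  if (length(aa) < n_v + n_j) {
    stop("canonical_cdr3a shorter than the templated V/J ends")
  }
  if (translate_nt(v_part) != paste(aa[seq_len(n_v)], collapse = "") ||
      translate_nt(j_part) !=
        paste(aa[seq(length(aa) - n_j + 1L, length(aa))], collapse = "")) {
    stop("canonical_cdr3a is incompatible with the TRAV11/TRAJ18 ",
         "templated junction ends (default: '", CANONICAL_CDR3A, "')")
  }
  middle <- aa[seq(n_v + 1L, length(aa) - n_j)]
  if (!all(middle %in% names(AA_TO_CODON))) {
    stop("canonical_cdr3a contains a non-standard residue")
  }
  paste0(v_part, paste(AA_TO_CODON[middle], collapse = ""), j_part)
}

#' @export
print.sim_repertoire <- function(x, ...) {
  r <- x$rearrangements
  cat("Synthetic", x$preset$name, "repertoire:", x$n_clonotypes,
      "clonotypes (seed", paste0(x$seed, ")\n"))
  cat("  records:", nrow(r), " (", sum(r$locus == "TRB"), "TRB /",
      sum(r$locus == "TRA"), "TRA )\n")
  cat("  productive TRB fraction:",
      round(mean(r$productive[r$locus == "TRB"]), 3), "\n")
  invisible(x)
}
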