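# Germline V/J reference segments with CDR3 anchor annotations.
#
# The CDR3 junction convention is inclusive: it starts at the first base of
# the conserved V cysteine codon (TGT/TGC) and ends at the last base of the
# conserved J phenylalanine/tryptophan codon of the [FW]GXG motif. Anchor
# offsets are 0-based positions of the first base of the anchor codon within
# the segment sequence.

#' Read a germline V/J reference FASTA
#'
#' Parses a germline reference FASTA whose headers carry the segment type and
#' anchor offset, e.g. `>TRBV13-2 type=V cys_anchor=54` or
#' `>TRBJ2-7 type=J phe_anchor=9`. Anchors are validated: every V cysteine
#' anchor codon must be TGT/TGC and every J anchor codon must be TTT/TTC/TGG
#' followed in frame by the GGN-XXN-GGN part of the `[FW]GXG` motif.
#'
#' @param path Path to the FASTA file.
#' @return A `germline_reference` object: a list with data frames
#'   `v_segments` (`gene`, `sequence`, `cys_anchor`) and `j_segments`
#'   (`gene`, `sequence`, `phe_anchor`).
#' @seealso [toy_germline()]
#' @export
read_germline <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  gene <- sub("\\s.*$", "", headers)
  type <- sub(".*type=([VJ]).*", "\\1", headers)
  if (!all(type %in% c("V", "J"))) {
    stop("germline FASTA headers must carry type=V or type=J")
  }
  anchor <- suppressWarnings(as.integer(sub(".*_anchor=([0-9]+).*", "\\1",
                                            headers)))
  if (anyNA(anchor)) stop("germline FASTA headers must carry an anchor offset")
  seq_chr <- as.character(seqs)
  v <- data.frame(gene = gene[type == "V"], sequence = seq_chr[type == "V"],
                  cys_anchor = anchor[type == "V"], stringsAsFactors = FALSE)
  j <- data.frame(gene = gene[type == "J"], sequence = seq_chr[type == "J"],
                  phe_anchor = anchor[type == "J"], stringsAsFactors = FALSE)
  ref <- structure(list(v_segments = v, j_segments = j),
                   class = "germline_reference")
  validate_germline(ref)
  ref
}

validate_germline <- function(ref) {
  v <- ref$v_segments
  j <- ref$j_segments
  if (nrow(v) == 0L || nrow(j) == 0L) {
    stop("germline reference must contain at least one V and one J segment")
  }
  cys <- substr(v$sequence, v$cys_anchor + 1L, v$cys_anchor + 3L)
  if (!all(cys %in% c("TGT", "TGC"))) {
    stop("V segment without TGT/TGC codon at its cys anchor: ",
         paste(v$gene[!cys %in% c("TGT", "TGC")], collapse = ", "))
  }
  phe <- substr(j$sequence, j$phe_anchor + 1L, j$phe_anchor + 3L)
  if (!all(phe %in% c("TTT", "TTC", "TGG"))) {
    stop("J segment without TTT/TTC/TGG codon at its phe anchor: ",
         paste(j$gene[!phe %in% c("TTT", "TTC", "TGG")], collapse = ", "))
  }
  motif_ok <- has_fgxg_motif(j$sequence, j$phe_anchor)
  if (!all(motif_ok)) {
    stop("J segment anchor not followed by the [FW]GXG motif: ",
         paste(j$gene[!motif_ok], collapse = ", "))
  }
  invisible(ref)
}

# [FW]GXG check: anchor codon then GGN, XXN, GGN in frame
has_fgxg_motif <- function(seq, phe_anchor) {
  anchor_aa <- substr(seq, phe_anchor + 1L, phe_anchor + 3L) %in%
    c("TTT", "TTC", "TGG")
  g1 <- substr(seq, phe_anchor + 4L, phe_anchor + 5L) == "GG"
  g2 <- substr(seq, phe_anchor + 10L, phe_anchor + 11L) == "GG"
  anchor_aa & g1 & g2 & nchar(seq) >= phe_anchor + 12L
}

#' Built-in synthetic toy germline reference
#'
#' Loads the synthetic germline reference shipped with the package: seven
#' TRBV segments (named after the Vbeta genes profiled in mouse iNKT
#' studies, plus a `TRBVother` catch-all), three TRBJ, two TRAV (TRAV11 and
#' TRAV10) and two TRAJ (TRAJ18 and TRAJ9) segments of 60 nt each with valid
#' CDR3 anchors. The sequences are synthetic stand-ins, not IMGT alleles;
#' any real reference in the same annotated-FASTA form is accepted by the
#' pipeline instead.
#'
#' @return A `germline_reference` object.
#' @export
toy_germline <- function() {
  read_germline(system.file("extdata", "toy_germline_synthetic.fasta",
                            package = "repsim", mustWork = TRUE))
}

#' @export
print.germline_reference <- function(x, ...) {
  cat("Germline reference:", nrow(x$v_segments), "V segments,",
      nrow(x$j_segments), "J segments\n")
  cat("  V:", paste(x$v_segments$gene, collapse = ", "), "\n")
  cat("  J:", paste(x$j_segments$gene, collapse = ", "), "\n")
  invisible(x)
}

germline_v <- function(ref, gene) {
  i <- match(gene, ref$v_segments$gene)
  if (is.na(i)) stop("unknown V gene: ", gene)
  ref$v_segments[i, ]
}

germline_j <- function(ref, gene) {
  i <- match(gene, ref$j_segments$gene)
  if (is.na(i)) stop("unknown J gene: ", gene)
  ref$j_segments[i, ]
}
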