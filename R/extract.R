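# Toy-scale CDR3 extraction: anchored prefix/suffix gene assignment,
# junction extraction between the conserved Cys and Phe/Trp anchors,
# productivity classification and rejects handling.
#
# Reads are assumed to start at the V segment start and end at the J segment
# end, as produced by the generator; gene assignment is exact/near-exact
# Hamming matching (default tolerance 2 mismatches), not local alignment.
# Records failing V or J assignment are reported as rejects with a reason
# code, never silently dropped.

hamming_str <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Assign the V gene of a read
#'
#' Compares each reference V prefix (through the end of its conserved Cys
#' codon) with the start of the read and returns the gene with the fewest
#' mismatches; ties are broken by gene-name lexicographic order.
#'
#' @param seq A nucleotide read.
#' @param germline A `germline_reference`.
#' @param max_mismatch Maximum tolerated mismatches (default 2); above it
#'   the read is unassignable.
#' @return List with `v_call` (NA if unassignable), `mismatches` and
#'   `cys_offset` (0-based offset of the Cys codon in the read).
#' @export
assign_v <- function(seq, germline, max_mismatch = 2L) {
  v <- germline$v_segments[order(germline$v_segments$gene), ]
  plen <- v$cys_anchor + 3L
  mm <- vapply(seq_len(nrow(v)), function(i) {
    if (nchar(seq) < plen[i]) return(Inf)
    hamming_str(substr(seq, 1L, plen[i]), substr(v$sequence[i], 1L, plen[i]))
  }, numeric(1))
  best <- which.min(mm)  # first index on ties = lexicographic order
  if (!is.finite(mm[best]) || mm[best] > max_mismatch) {
    return(list(v_call = NA_character_, mismatches = NA_integer_,
                cys_offset = NA_integer_))
  }
  list(v_call = v$gene[best], mismatches = as.integer(mm[best]),
       cys_offset = v$cys_anchor[best])
}

#' Assign the J gene of a read
#'
#' Suffix analogue of [assign_v()]: each reference J's anchor-containing
#' suffix (from its Phe/Trp anchor to the segment end) is compared with the
#' read tail; fewest mismatches wins, ties broken lexicographically.
#'
#' @inheritParams assign_v
#' @return List with `j_call` (NA if unassignable) and `mismatches`.
#' @export
assign_j <- function(seq, germline, max_mismatch = 2L) {
  j <- germline$j_segments[order(germline$j_segments$gene), ]
  suf <- substr(j$sequence, j$phe_anchor + 1L, nchar(j$sequence))
  slen <- nchar(suf)
  mm <- vapply(seq_len(nrow(j)), function(i) {
    if (nchar(seq) < slen[i]) return(Inf)
    hamming_str(substr(seq, nchar(seq) - slen[i] + 1L, nchar(seq)), suf[i])
  }, numeric(1))
  best <- which.min(mm)
  if (!is.finite(mm[best]) || mm[best] > max_mismatch) {
    return(list(j_call = NA_character_, mismatches = NA_integer_))
  }
  list(j_call = j$gene[best], mismatches = as.integer(mm[best]))
}

#' Locate the J Phe/Trp anchor in a read
#'
#' Finds the 0-based offset of the first base of the conserved Phe/Trp
#' codon by locating the assigned J's anchor-containing suffix in the read
#' (minimum-Hamming scan; on ties the rightmost position wins, which is
#' where the J belongs). The anchor is validated against the `[FW]GXG`
#' motif in the frame it implies.
#'
#' @inheritParams assign_v
#' @param j_call J gene name, as assigned by [assign_j()].
#' @return 0-based anchor offset, or `NA` if the motif cannot be located
#'   within `max_mismatch`.
#' @export
locate_j_anchor <- function(seq, germline, j_call, max_mismatch = 2L) {
  j <- germline_j(germline, j_call)
  suf <- substr(j$sequence, j$phe_anchor + 1L, nchar(j$sequence))
  slen <- nchar(suf)
  if (nchar(seq) < slen) return(NA_integer_)
  starts <- seq_len(nchar(seq) - slen + 1L)
  mm <- vapply(starts, function(i)
    hamming_str(substr(seq, i, i + slen - 1L), suf), numeric(1))
  ok <- which(mm <= max_mismatch)
  if (length(ok) == 0L) return(NA_integer_)
  # rightmost among the minimal-mismatch positions
  best <- max(ok[mm[ok] == min(mm[ok])])
  offset <- best - 1L
  if (!has_fgxg_motif(seq, offset)) return(NA_integer_)
  offset
}

#' Extract the CDR3 junction between anchors
#'
#' Returns the read substring from the first base of the Cys codon through
#' the last base of the Phe/Trp codon, inclusive (length
#' `phe_offset - cys_offset + 3`). Offsets are 0-based.
#'
#' @param seq A nucleotide read.
#' @param cys_offset,phe_offset 0-based offsets of the first base of the V
#'   Cys codon and of the J Phe/Trp codon; `cys_offset <= phe_offset`.
#' @return Junction nucleotide string.
#' @export
extract_junction <- function(seq, cys_offset, phe_offset) {
  if (phe_offset < cys_offset) {
    stop("phe_offset must not precede cys_offset")
  }
  substr(seq, cys_offset + 1L, phe_offset + 3L)
}

#' Classify junction productivity
#'
#' A junction is productive iff its length is a multiple of 3 and its
#' translation contains no stop codon. The amino-acid junction is returned
#' only for productive junctions (empty string otherwise).
#'
#' @param junction Character vector of junction nucleotide strings.
#' @return List with logical vector `productive` and character vector
#'   `junction_aa`.
#' @examples
#' classify_productive("TGTGCAAGCAGTTTT")  # productive, "CASSF"
#' @export
classify_productive <- function(junction) {
  if (any(nchar(junction) == 0L)) stop("empty junction")
  if (any(grepl("[^ACGT]", junction))) {
    stop("invalid character in junction (alphabet is A,C,G,T)")
  }
  in_frame <- nchar(junction) %% 3L == 0L
  aa <- character(length(junction))
  if (any(in_frame)) aa[in_frame] <- translate_nt(junction[in_frame])
  productive <- in_frame & !grepl("*", aa, fixed = TRUE)
  aa[!productive] <- ""
  list(productive = productive, junction_aa = aa)
}

#' Extract rearrangements from raw reads
#'
#' Runs the full extraction stage on a set of reads: V assignment by
#' anchored prefix matching, J assignment by anchored suffix matching,
#' junction extraction between the conserved anchors, and productivity
#' classification. Reads failing V or J assignment or anchor-motif
#' validation are returned as rejects with a reason code.
#'
#' @param reads Either a character vector of nucleotide sequences (names
#'   used as sequence ids), the path to a FASTA file, or a data frame with
#'   a `sequence` column (e.g. an AIRR table; `sequence_id`,
#'   `duplicate_count`, `sample_id` and `tissue` are carried through).
#' @param germline A `germline_reference`.
#' @param max_mismatch Mismatch tolerance for gene assignment (default 2).
#' @return List with `rearrangements` (AIRR-style data frame) and `rejects`
#'   (data frame with `sequence_id`, `sequence`, `reason`).
#' @export
extract_rearrangements <- function(reads, germline, max_mismatch = 2L) {
  meta <- NULL
  if (is.data.frame(reads)) {
    meta <- reads
    seqs <- reads$sequence
    ids <- if ("sequence_id" %in% names(reads)) reads$sequence_id else
      sprintf("read%06d", seq_along(seqs))
  } else if (is.character(reads) && length(reads) == 1L &&
             file.exists(reads) && !grepl("^[ACGT]+$", reads)) {
    fa <- Biostrings::readDNAStringSet(reads)
    seqs <- as.character(fa)
    ids <- sub("\\s.*$", "", names(fa))
  } else {
    seqs <- reads
    ids <- if (!is.null(names(reads))) names(reads) else
      sprintf("read%06d", seq_along(seqs))
  }
  n <- length(seqs)
  if (n == 0L) stop("no reads supplied")

  v <- germline$v_segments[order(germline$v_segments$gene), ]
  j <- germline$j_segments[order(germline$j_segments$gene), ]
  v_mm <- batch_mismatch(seqs, substr(v$sequence, 1L, v$cys_anchor + 3L),
                         side = "prefix")
  j_suf <- substr(j$sequence, j$phe_anchor + 1L, nchar(j$sequence))
  j_mm <- batch_mismatch(seqs, j_suf, side = "suffix")

  v_best <- max.col(-v_mm, ties.method = "first")
  v_bestmm <- v_mm[cbind(seq_len(n), v_best)]
  j_best <- max.col(-j_mm, ties.method = "first")
  j_bestmm <- j_mm[cbind(seq_len(n), j_best)]

  reason <- rep(NA_character_, n)
  reason[!is.finite(v_bestmm) | v_bestmm > max_mismatch] <- "v_unassignable"
  ok_v <- is.na(reason)
  ok_j <- is.finite(j_bestmm) & j_bestmm <= max_mismatch
  reason[ok_v & !ok_j] <- "j_unassignable"

  cys_off <- v$cys_anchor[v_best]
  phe_off <- nchar(seqs) - nchar(j_suf[j_best])
  motif_ok <- has_fgxg_motif(seqs, phe_off)
  reason[is.na(reason) & !motif_ok] <- "anchor_motif_not_found"

  keep <- is.na(reason)
  rejects <- data.frame(sequence_id = ids[!keep], sequence = seqs[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  if (!any(keep)) {
    return(list(rearrangements = empty_airr(), rejects = rejects))
  }

  junction <- substr(seqs[keep], cys_off[keep] + 1L, phe_off[keep] + 3L)
  cls <- classify_productive(junction)
  out <- data.frame(
    sequence_id = ids[keep],
    sequence = seqs[keep],
    v_call = v$gene[v_best[keep]],
    d_call = "",
    j_call = j$gene[j_best[keep]],
    junction = junction,
    junction_aa = cls$junction_aa,
    productive = cls$productive,
    duplicate_count = 1L,
    locus = ifelse(startsWith(v$gene[v_best[keep]], "TRA"), "TRA", "TRB"),
    sample_id = "", tissue = "",
    stringsAsFactors = FALSE
  )
  if (!is.null(meta)) {
    for (col in c("duplicate_count", "sample_id", "tissue")) {
      if (col %in% names(meta)) out[[col]] <- meta[[col]][keep]
    }
  }
  list(rearrangements = out, rejects = rejects)
}

# per-reference-segment mismatch counts for a batch of reads: the read
# prefix (or suffix) of each reference's length is compared with it; exact
# matches short-circuit, the remainder are compared character-wise
batch_mismatch <- function(seqs, ref_parts, side = c("prefix", "suffix")) {
  side <- match.arg(side)
  n <- length(seqs)
  k <- length(ref_parts)
  mm <- matrix(Inf, nrow = n, ncol = k)
  len <- nchar(seqs)
  for (col in seq_len(k)) {
    ref <- ref_parts[col]
    L <- nchar(ref)
    part <- if (side == "prefix") substr(seqs, 1L, L) else
      substr(seqs, pmax(len - L + 1L, 1L), len)
    fits <- len >= L
    exact <- fits & part == ref
    mm[exact, col] <- 0
    todo <- which(fits & !exact)
    if (length(todo) > 0L) {
      ref_int <- utf8ToInt(ref)
      mm[todo, col] <- vapply(part[todo],
                              function(s) sum(utf8ToInt(s) != ref_int),
                              numeric(1), USE.NAMES = FALSE)
    }
  }
  mm
}

empty_airr <- function() {
  data.frame(sequence_id = character(0), sequence = character(0),
             v_call = character(0), d_call = character(0),
             j_call = character(0), junction = character(0),
             junction_aa = character(0), productive = logical(0),
             duplicate_count = integer(0), locus = character(0),
             sample_id = character(0), tissue = character(0),
             stringsAsFactors = FALSE)
}

#' Assemble clonotypes from rearrangement records
#'
#' Groups productive rearrangements by a clonotype key (default: V gene +
#' CDR3 nucleotide junction) and sums their duplicate counts. With
#' `scope = "per_sample"` grouping is additionally by `sample_id`; with
#' `scope = "pooled"` samples of a tissue are merged before assembly.
#' Output is sorted by count descending, then key ascending.
#'
#' @param records AIRR-style rearrangement data frame. Nonproductive
#'   records are dropped (with a message) before assembly.
#' @param key Character vector of grouping columns; default
#'   `c("v_call", "junction")`. Add `"j_call"` or use `"junction_aa"` for
#'   alternative clonotype definitions.
#' @param scope `"per_sample"` (default) or `"pooled"`.
#' @return Data frame with columns `v_call`, `j_call`, `cdr3_nt`,
#'   `cdr3_aa`, `count`, `sample_id`, `tissue`.
#' @export
assemble_clonotypes <- function(records, key = c("v_call", "junction"),
                                scope = c("per_sample", "pooled")) {
  scope <- match.arg(scope)
  stopifnot(is.data.frame(records), all(key %in% names(records)))
  if (nrow(records) == 0L) stop("empty rearrangement table")
  n_nonprod <- sum(!records$productive)
  if (n_nonprod > 0L) {
    message("dropping ", n_nonprod, " nonproductive record(s) before assembly")
    records <- records[records$productive, , drop = FALSE]
  }
  if (nrow(records) == 0L) stop("no productive records to assemble")
  group_cols <- key
  if (scope == "per_sample" && "sample_id" %in% names(records)) {
    group_cols <- c(group_cols, "sample_id")
  }
  grp <- interaction(records[group_cols], drop = TRUE, sep = "\r")
  idx <- split(seq_len(nrow(records)), grp)
  first <- vapply(idx, `[[`, 0L, 1L)
  out <- data.frame(
    v_call = records$v_call[first],
    j_call = records$j_call[first],
    cdr3_nt = records$junction[first],
    cdr3_aa = records$junction_aa[first],
    count = vapply(idx, function(i)
      sum(as.integer(records$duplicate_count[i])), 0L),
    sample_id = if (scope == "per_sample" && "sample_id" %in% names(records))
      records$sample_id[first] else "pooled",
    tissue = if ("tissue" %in% names(records)) records$tissue[first] else "",
    stringsAsFactors = FALSE
  )
  ord <- order(-out$count, out$v_call, out$cdr3_nt, out$sample_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
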