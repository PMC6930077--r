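#' Translate in-frame nucleotide sequences
#'
#' Standard-genetic-code translation of nucleotide strings whose length is a
#' multiple of 3. Stop codons are rendered as `*`. Delegates to
#' [Biostrings::translate()].
#'
#' @param nt Character vector of nucleotide sequences over `{A,C,G,T}`.
#' @return Character vector of amino-acid sequences.
#' @examples
#' translate_nt("TGTGCAAGCAGTTTT")  # "CASSF"
#' @export
translate_nt <- function(nt) {
  if (length(nt) == 0L) return(character(0))
  if (anyNA(nt)) stop("NA sequence in `nt`")
  bad_frame <- nchar(nt) %% 3L != 0L
  if (any(bad_frame)) {
    stop("sequence length not a multiple of 3 at position ",
         which(bad_frame)[1L])
  }
  if (any(grepl("[^ACGT]", nt))) {
    stop("invalid character (alphabet is A,C,G,T) at position ",
         which(grepl("[^ACGT]", nt))[1L])
  }
  empty <- nchar(nt) == 0L
  out <- character(length(nt))
  if (any(!empty)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(nt[!empty]),
                                no.init.codon = TRUE)
    out[!empty] <- as.character(aa)
  }
  out
}
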