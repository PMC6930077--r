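# AIRR Rearrangement TSV input/output.
#
# One row per sequenced rearrangement, columns named after the AIRR
# Rearrangement schema. Round-trips must be lossless: booleans are written as
# T/F, counts as integers, and all other fields as plain strings.

AIRR_MANDATORY <- c("sequence_id", "sequence", "v_call", "d_call", "j_call",
                    "junction", "junction_aa", "productive", "duplicate_count",
                    "locus")
AIRR_OPTIONAL <- c("sample_id", "tissue")

#' Read an AIRR Rearrangement TSV
#'
#' Reads a tab-separated rearrangement table with AIRR schema column names.
#' The `productive` column is parsed from `T`/`F` or `true`/`false`; a
#' missing `duplicate_count` value defaults to 1.
#'
#' @param path Path to a tab-separated file with a header row containing at
#'   least the mandatory AIRR columns (`sequence_id`, `sequence`, `v_call`,
#'   `d_call`, `j_call`, `junction`, `junction_aa`, `productive`,
#'   `duplicate_count`, `locus`); `sample_id` and `tissue` are optional.
#' @return A data frame with one row per rearrangement, `productive` logical
#'   and `duplicate_count` integer.
#' @seealso [write_airr()]
#' @export
read_airr <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   na.strings = NULL, check.names = FALSE,
                   comment.char = "#", quote = "")
  missing_cols <- setdiff(AIRR_MANDATORY, names(df))
  if (length(missing_cols) > 0L) {
    stop("AIRR format error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$productive <- parse_airr_bool(df$productive)
  dc <- df$duplicate_count
  dc[dc == ""] <- "1"
  bad <- !grepl("^[0-9]+$", dc)
  if (any(bad)) {
    stop("non-integer duplicate_count in row ", which(bad)[1L],
         ": '", dc[which(bad)[1L]], "'")
  }
  df$duplicate_count <- as.integer(dc)
  df
}

parse_airr_bool <- function(x) {
  up <- toupper(x)
  out <- rep(NA, length(x))
  out[up %in% c("T", "TRUE")] <- TRUE
  out[up %in% c("F", "FALSE")] <- FALSE
  if (anyNA(out) && length(x) > 0L) {
    stop("unparseable boolean value '", x[which(is.na(out))[1L]],
         "' in column productive")
  }
  as.logical(out)
}

#' Write an AIRR Rearrangement TSV
#'
#' Writes a rearrangement data frame as a tab-separated AIRR table.
#' `read_airr(write_airr(x, path))` reproduces every field exactly.
#'
#' @param records Data frame as returned by [read_airr()] or
#'   [simulate_repertoire()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(records, path) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(AIRR_MANDATORY, names(records))
  if (length(missing_cols) > 0L) {
    stop("records lack mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- records
  out$productive <- ifelse(out$productive, "T", "F")
  out$duplicate_count <- as.integer(out$duplicate_count)
  ok <- tryCatch({
    write.table(out, file = path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}
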