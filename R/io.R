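# CSV/TSV readers and writers for sample tables.

sniff_sep <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read binding samples from CSV/TSV
#'
#' Reads a delimited table (comma by default; tab for `.tsv`/`.txt`) with the
#' canonical columns `peptide, cdr3b, cdr3a, mhc, va, ja, vb, db, jb, label,
#' source, negative_origin` (only the setting's identity fields and `label`
#' are mandatory). Sequence fields are case-normalised and validated against
#' the 20-letter amino-acid alphabet; rows failing validation are dropped and
#' counted in the `"dropped_invalid"` attribute of the result.
#'
#' @param path Path to an existing CSV/TSV file with a header row.
#' @param setting Tuple-identity setting; see [setting()].
#' @param quiet Suppress the dropped-row message.
#' @return A [sample_table()]; `attr(x, "dropped_invalid")` holds the number
#'   of rows removed by sequence validation.
#' @export
read_samples <- function(path, setting = "pep_cdr3b", quiet = FALSE) {
  setting <- setting(setting)
  if (!file.exists(path)) {
    tb_stop("tcrbench_file_not_found", sprintf("file not found: %s", path))
  }
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          colClasses = "character", na.strings = NULL,
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c(unclass(setting), "label"), names(df))
  if (length(miss)) {
    tb_stop("tcrbench_missing_column",
            sprintf("missing required column(s) in %s: %s", path,
                    paste(miss, collapse = ", ")))
  }
  df$label <- suppressWarnings(as.integer(df$label))
  ok <- !is.na(df$label) & df$label %in% c(0L, 1L)
  for (col in intersect(c("peptide", "cdr3b"), names(df))) {
    ok <- ok & valid_seq_mask(df[[col]])
  }
  if ("cdr3a" %in% names(df)) {
    ok <- ok & valid_seq_mask(df$cdr3a, allow_empty = TRUE)
  }
  dropped <- sum(!ok)
  if (dropped && !quiet) {
    message(sprintf("read_samples: dropped %d row(s) failing validation", dropped))
  }
  out <- sample_table(df[ok, , drop = FALSE], setting = setting)
  attr(out, "dropped_invalid") <- dropped
  out
}

#' Write binding samples to CSV/TSV
#'
#' Writes the canonical schema so that [read_samples()] recovers the table
#' field-for-field (missing optional fields round-trip as empty cells).
#'
#' @param table A [sample_table()].
#' @param path Output path; `.tsv`/`.txt` selects tab separation.
#' @return `path`, invisibly.
#' @export
write_samples <- function(table, path) {
  stopifnot(inherits(table, "sample_table"))
  utils::write.table(as.data.frame(table), path, sep = sniff_sep(path),
                     row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
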