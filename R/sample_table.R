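# Sample data model: settings, sequence validation, sample_table container.

# Canonical column order of the on-disk schema.
SCHEMA_COLS <- c("peptide", "cdr3b", "cdr3a", "mhc", "va", "ja", "vb", "db",
                 "jb", "label", "source", "negative_origin")

#' Declare which fields define tuple identity
#'
#' A *setting* is the ordered subset of `{peptide, cdr3b, cdr3a, mhc}` that
#' defines the identity of a binding tuple. The two standard settings are
#' `(peptide, cdr3b)` and `(peptide, cdr3b, cdr3a, mhc)`; any user subset
#' containing `peptide` and `cdr3b` is accepted.
#'
#' @param x Either a shorthand name (`"pep_cdr3b"` or `"paired_mhc"`) or a
#'   character vector of identity fields.
#' @return A character vector of identity fields, classed `"tcr_setting"`.
#' @examples
#' setting("pep_cdr3b")
#' setting(c("peptide", "cdr3b", "mhc"))
#' @export
setting <- function(x = "pep_cdr3b") {
  if (inherits(x, "tcr_setting")) return(x)
  if (length(x) == 1 && x %in% c("pep_cdr3b", "paired_mhc")) {
    x <- switch(x,
      pep_cdr3b = c("peptide", "cdr3b"),
      paired_mhc = c("peptide", "cdr3b", "cdr3a", "mhc")
    )
  }
  allowed <- c("peptide", "cdr3b", "cdr3a", "mhc")
  if (!all(x %in% allowed)) {
    tb_stop("tcrbench_bad_setting",
            sprintf("setting fields must be a subset of {%s}",
                    paste(allowed, collapse = ", ")))
  }
  if (!all(c("peptide", "cdr3b") %in% x)) {
    tb_stop("tcrbench_bad_setting",
            "a setting must contain at least 'peptide' and 'cdr3b'")
  }
  structure(allowed[allowed %in% x], class = "tcr_setting")
}

#' Validate an amino-acid sequence
#'
#' Strips surrounding whitespace, upper-cases, and checks that every residue
#' is one of the 20 standard amino acids (`ACDEFGHIKLMNPQRSTVWY`). The
#' ambiguity codes B, J, O, U, X, Z and the stop character `*` are rejected.
#' Idempotent: `validate_sequence(validate_sequence(s)) == validate_sequence(s)`.
#'
#' @param seq A single character string.
#' @param kind `"peptide"` or `"cdr3"`; used only in error messages.
#' @return The validated uppercase sequence.
#' @examples
#' validate_sequence("casSirssyeqyf", "cdr3")
#' @export
validate_sequence <- function(seq, kind = c("peptide", "cdr3")) {
  kind <- match.arg(kind)
  if (length(seq) != 1 || is.na(seq)) {
    tb_stop("tcrbench_empty_sequence", "seq must be a single non-NA string")
  }
  s <- toupper(trimws(seq))
  if (!nzchar(s)) {
    tb_stop("tcrbench_empty_sequence",
            sprintf("empty %s sequence", kind))
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA20)
  if (length(bad)) {
    # first offending residue under a left-to-right scan
    tb_stop("tcrbench_invalid_residue",
            sprintf("invalid residue '%s' at position %d in %s sequence '%s'",
                    chars[bad[1]], bad[1], kind, s),
            residue = chars[bad[1]], position = bad[1])
  }
  s
}

# Vectorised validity mask used by the readers (same rule as validate_sequence).
valid_seq_mask <- function(x, allow_empty = FALSE) {
  x <- toupper(trimws(x))
  ok <- grepl(sprintf("^[%s]+$", paste(AA20, collapse = "")), x)
  if (allow_empty) ok <- ok | !nzchar(x)
  ok
}

#' Construct a table of binding samples
#'
#' A `sample_table` is a data frame with one row per (peptide, CDR3beta\[,
#' CDR3alpha\]\[, MHC\]\[, V/(D)/J genes\]) tuple, a binary binding `label`
#' (1 = binding), a free-text `source` tag, and a `negative_origin` marker
#' (`"none"` for positives, `"NA"` for assay-derived negatives, `"RN"` for
#' recombined negatives). Missing optional fields are empty strings. The
#' declared [setting()] travels with the table as an attribute.
#'
#' @param df A data frame containing at least `peptide`, `cdr3b` and `label`.
#'   Unknown extra columns (e.g. a quality score) are preserved.
#' @param setting The tuple-identity setting; see [setting()].
#' @param validate Validate/uppercase sequence columns (default `TRUE`).
#' @return A data frame of class `c("sample_table", "data.frame")`.
#' @examples
#' tab <- sample_table(data.frame(peptide = "NLVPMVATV",
#'                                cdr3b = "CASSIRSSYEQYF", label = 1))
#' @export
sample_table <- function(df, setting = "pep_cdr3b", validate = TRUE) {
  setting <- setting(setting)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  miss <- setdiff(c(unclass(setting), "label"), names(df))
  if (length(miss)) {
    tb_stop("tcrbench_missing_column",
            sprintf("missing required column(s): %s",
                    paste(miss, collapse = ", ")))
  }
  for (col in setdiff(SCHEMA_COLS, names(df))) {
    df[[col]] <- if (col == "label") NA_integer_ else ""
  }
  seq_cols <- c("peptide", "cdr3b", "cdr3a", "mhc", "va", "ja", "vb", "db",
                "jb", "source", "negative_origin")
  for (col in seq_cols) {
    v <- as.character(df[[col]])
    v[is.na(v)] <- ""
    df[[col]] <- v
  }
  df$label <- as.integer(df$label)
  if (any(is.na(df$label)) || !all(df$label %in% c(0L, 1L))) {
    tb_stop("tcrbench_bad_label", "label must be 0 or 1 for every row")
  }
  if (validate) {
    df$peptide <- toupper(trimws(df$peptide))
    df$cdr3b <- toupper(trimws(df$cdr3b))
    df$cdr3a <- toupper(trimws(df$cdr3a))
    ok <- valid_seq_mask(df$peptide) & valid_seq_mask(df$cdr3b) &
      valid_seq_mask(df$cdr3a, allow_empty = TRUE)
    if (!all(ok)) {
      tb_stop("tcrbench_invalid_residue",
              sprintf("%d row(s) contain invalid residues; use read_samples() to drop them",
                      sum(!ok)))
    }
  }
  # positives carry no negative origin; untagged negatives default to assay ("NA")
  df$negative_origin[df$label == 1L] <- "none"
  fix <- df$label == 0L & !df$negative_origin %in% c("NA", "RN")
  df$negative_origin[fix] <- "NA"
  extra <- setdiff(names(df), SCHEMA_COLS)
  df <- df[, c(SCHEMA_COLS, extra), drop = FALSE]
  rownames(df) <- NULL
  structure(df, setting = setting,
            class = c("sample_table", "data.frame"))
}

#' @export
print.sample_table <- function(x, ...) {
  st <- attr(x, "setting")
  cat(sprintf("<sample_table> %d samples (%d positive, %d negative); setting: (%s)\n",
              nrow(x), sum(x$label == 1L), sum(x$label == 0L),
              paste(st, collapse = ", ")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

# Subsetting keeps class and setting.
#' @export
`[.sample_table` <- function(x, i, ...) {
  st <- attr(x, "setting")
  out <- NextMethod()
  if (is.data.frame(out)) {
    rownames(out) <- NULL
    attr(out, "setting") <- st
    class(out) <- c("sample_table", "data.frame")
  }
  out
}

tbl_setting <- function(table) {
  attr(table, "setting") %||% setting("pep_cdr3b")
}

# Row-identity keys under a setting (optionally including the label).
identity_key <- function(table, setting = tbl_setting(table),
                         with_label = FALSE) {
  fields <- unclass(setting(setting))
  parts <- lapply(fields, function(f) table[[f]])
  if (with_label) parts <- c(parts, list(table$label))
  do.call(paste, c(parts, sep = "\r"))
}
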