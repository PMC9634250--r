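# BLOSUM50 sequence encoding and MHC pseudo-sequence handling.

the <- new.env(parent = emptyenv())

#' The BLOSUM50 substitution matrix
#'
#' The canonical published BLOSUM50 matrix restricted to the 20 standard
#' residues, rows and columns in fixed alphabetical one-letter order.
#'
#' @return A 20 x 20 integer matrix.
#' @export
blosum50_matrix <- function() {
  if (is.null(the$blosum50)) {
    path <- system.file("extdata", "blosum50.txt", package = "tcrbench")
    m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1,
                                     check.names = FALSE))
    storage.mode(m) <- "integer"
    stopifnot(identical(rownames(m), AA20), identical(colnames(m), AA20))
    the$blosum50 <- m
  }
  the$blosum50
}

#' Encoding settings
#'
#' Per-field maximum lengths default to the dataset builder's length-filter
#' bounds (peptide 15, CDR3beta 23, CDR3alpha 21) plus the conventional
#' 34-residue MHC pseudo-sequence, so no post-filter sequence can overflow.
#'
#' @param matrix Substitution matrix name; only `"BLOSUM50"` is bundled.
#' @param max_len_peptide,max_len_cdr3b,max_len_cdr3a,max_len_pseudo
#'   Padded lengths per field.
#' @param pad_value Fill value for padding rows (default 0).
#' @return An `encoding_config` list.
#' @export
encoding_config <- function(matrix = "BLOSUM50", max_len_peptide = 15L,
                            max_len_cdr3b = 23L, max_len_cdr3a = 21L,
                            max_len_pseudo = 34L, pad_value = 0) {
  if (!identical(matrix, "BLOSUM50")) {
    tb_stop("tcrbench_config_error", "only the BLOSUM50 matrix is bundled")
  }
  structure(list(matrix = matrix,
                 max_len_peptide = as.integer(max_len_peptide),
                 max_len_cdr3b = as.integer(max_len_cdr3b),
                 max_len_cdr3a = as.integer(max_len_cdr3a),
                 max_len_pseudo = as.integer(max_len_pseudo),
                 pad_value = pad_value),
            class = "encoding_config")
}

#' BLOSUM50-encode one sequence
#'
#' Row `i` of the result (for `i <= nchar(seq)`) is the BLOSUM50 substitution
#' score vector of residue `i` against the 20 standard residues in
#' alphabetical order; remaining rows are `pad_value` (right padding).
#'
#' @param seq A validated amino-acid string.
#' @param max_len Padded length; `nchar(seq)` must not exceed it.
#' @param cfg An [encoding_config()].
#' @return A `max_len x 20` numeric matrix.
#' @examples
#' blosum_encode("A", 3)[1, "A"]  # 5, the BLOSUM50 A->A score
#' @export
blosum_encode <- function(seq, max_len, cfg = encoding_config()) {
  seq <- validate_sequence(seq, "peptide")
  n <- nchar(seq)
  if (n > max_len) {
    tb_stop("tcrbench_sequence_too_long",
            sprintf("sequence of length %d exceeds max_len %d", n, max_len))
  }
  out <- matrix(cfg$pad_value, nrow = max_len, ncol = 20,
                dimnames = list(NULL, AA20))
  out[seq_len(n), ] <- blosum50_matrix()[strsplit(seq, "")[[1]], ]
  out
}

#' Attach MHC pseudo-sequences to a table
#'
#' Adds a `pseudo` column by looking each row's MHC allele up in a
#' user-supplied allele-to-pseudo-sequence map (NetMHCpan-style; class I and
#' II alleles are treated identically). Rows with unmapped alleles are
#' dropped and counted, or raise, depending on `drop_missing`.
#'
#' @param table A [sample_table()] with a non-empty `mhc` column.
#' @param mhc_map Named character vector or two-column data frame
#'   (`allele`, `pseudo`) mapping alleles to pseudo-sequences.
#' @param drop_missing Drop (and count) rows with unmapped alleles instead of
#'   raising.
#' @return The table with a `pseudo` column; `attr(x, "n_unmapped")` counts
#'   dropped rows.
#' @export
attach_pseudo_sequence <- function(table, mhc_map, drop_missing = FALSE) {
  if (is.data.frame(mhc_map)) {
    mhc_map <- stats::setNames(as.character(mhc_map[[2]]),
                               as.character(mhc_map[[1]]))
  }
  pseudo <- unname(mhc_map[table$mhc])
  unmapped <- is.na(pseudo)
  if (any(unmapped) && !drop_missing) {
    tb_stop("tcrbench_unknown_allele",
            sprintf("%d row(s) carry alleles absent from mhc_map (e.g. '%s')",
                    sum(unmapped), table$mhc[which(unmapped)[1]]))
  }
  table$pseudo <- ifelse(unmapped, "", toupper(pseudo))
  out <- table[!unmapped, , drop = FALSE]
  attr(out, "n_unmapped") <- sum(unmapped)
  out
}

# Flattened per-row feature matrix: concatenated padded BLOSUM encodings of
# the setting's sequence fields. Values scaled by 1/5 for optimizer comfort.
encode_table <- function(table, enc = encoding_config(),
                         st = tbl_setting(table)) {
  fields <- list(peptide = enc$max_len_peptide, cdr3b = enc$max_len_cdr3b)
  if ("cdr3a" %in% unclass(st)) fields$cdr3a <- enc$max_len_cdr3a
  if ("mhc" %in% unclass(st) && "pseudo" %in% names(table) &&
      any(nzchar(table$pseudo))) {
    fields$pseudo <- enc$max_len_pseudo
  }
  B <- blosum50_matrix() / 5
  n <- nrow(table)
  blocks <- lapply(names(fields), function(f) {
    max_len <- fields[[f]]
    v <- table[[f]]
    lens <- nchar(v)
    if (any(lens > max_len)) {
      tb_stop("tcrbench_sequence_too_long",
              sprintf("%s sequence longer than %d", f, max_len))
    }
    X <- matrix(enc$pad_value / 5, n, max_len * 20)
    for (j in seq_len(max_len)) {
      idx <- which(lens >= j)
      if (!length(idx)) break
      X[idx, (j - 1L) * 20L + 1:20] <- B[substr(v[idx], j, j), , drop = FALSE]
    }
    X
  })
  do.call(cbind, blocks)
}
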