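# Class-distribution diagnostics: per-sequence class histograms,
# class-disjointness, and the CDR3-memorization oracle.

#' Per-sequence positive/negative occurrence counts
#'
#' For each unique value of `field` (peptide, CDR3beta or CDR3alpha), counts
#' how many positive and how many negative rows carry it. Sorted by total
#' count descending. When the positive and negative repertoires of a field
#' are disjoint (every sequence appears in only one class), a classifier can
#' label samples from that field alone, ignoring its partner — the
#' memorization shortcut these diagnostics exist to expose.
#'
#' @param table A [sample_table()].
#' @param field `"peptide"`, `"cdr3b"` or `"cdr3a"`.
#' @return A data frame of class `class_histogram` with columns `sequence`,
#'   `pos_count`, `neg_count`; empty-string entries (missing optional chain)
#'   are excluded.
#' @export
class_histogram <- function(table, field = c("cdr3b", "peptide", "cdr3a")) {
  field <- match.arg(field)
  if (is.null(table[[field]])) {
    tb_stop("tcrbench_missing_field", sprintf("field '%s' not in table", field))
  }
  v <- table[[field]]
  keep <- nzchar(v)
  v <- v[keep]
  lab <- table$label[keep]
  if (!length(v)) {
    out <- data.frame(sequence = character(0), pos_count = integer(0),
                      neg_count = integer(0))
  } else {
    pos <- table(factor(v[lab == 1L], levels = unique(v)))
    neg <- table(factor(v[lab == 0L], levels = unique(v)))
    out <- data.frame(sequence = unique(v),
                      pos_count = as.integer(pos),
                      neg_count = as.integer(neg))
    out <- out[order(-(out$pos_count + out$neg_count), out$sequence), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, field = field, class = c("class_histogram", "data.frame"))
}

#' Fraction of sequences occurring in both classes
#'
#' `0` means the positive and negative repertoires are fully disjoint — the
#' degenerate class structure under which memorizing sequences suffices for
#' near-perfect classification; `1` means every sequence occurs in both.
#'
#' @param hist A [class_histogram()].
#' @return A number in `[0, 1]`.
#' @export
disjointness_fraction <- function(hist) {
  if (nrow(hist) == 0L) {
    tb_stop("tcrbench_empty_histogram", "histogram has no entries")
  }
  mean(hist$pos_count > 0L & hist$neg_count > 0L)
}

#' CDR3-memorization oracle
#'
#' Scores each test row purely from its CDR3 (or other chosen field) by the
#' smoothed training-set positive frequency of that sequence:
#' `score = (pos_count + alpha * pi) / (total_count + alpha)` with `pi` the
#' training positive rate; a sequence never seen in training scores exactly
#' `pi`. The peptide column is ignored *by design*: the oracle is an
#' executable ceiling for how far pure sequence memorization can go, to be
#' reported next to any real model.
#'
#' @param train,test [sample_table()]s.
#' @param field Field to memorize (default `"cdr3b"`).
#' @param alpha Pseudo-count toward the training prior (default 1).
#' @return Numeric scores in `[0, 1]`, one per test row.
#' @export
memorization_oracle <- function(train, test, field = "cdr3b", alpha = 1) {
  if (nrow(train) == 0L) {
    tb_stop("tcrbench_empty_positives", "training table is empty")
  }
  h <- class_histogram(train, field)
  pi_hat <- mean(train$label == 1L)
  i <- match(test[[field]], h$sequence)
  pos <- ifelse(is.na(i), 0L, h$pos_count[i])
  tot <- ifelse(is.na(i), 0L, h$pos_count[i] + h$neg_count[i])
  as.numeric((pos + alpha * pi_hat) / (tot + alpha))
}
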