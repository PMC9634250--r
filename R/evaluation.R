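# Metric suite: AUROC (Mann-Whitney), AUPR (step integral), thresholded
# metrics, per-peptide AUROC, and aggregation over repeated splits.

# Rank-based AUROC with ties counted 1/2; NA when a class is absent.
auroc_mw <- function(labels, scores) {
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Non-interpolated precision-recall step integral over unique score cuts.
aupr_step <- function(labels, scores) {
  n1 <- sum(labels == 1L)
  if (n1 == 0L || all(labels == 1L)) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  tp <- cumsum(lab == 1L)
  fp <- cumsum(lab == 0L)
  # evaluate only at the last index of each tied score block
  cut <- c(which(diff(sc) != 0), length(sc))
  prec <- tp[cut] / (tp[cut] + fp[cut])
  rec <- tp[cut] / n1
  sum(diff(c(0, rec)) * prec)
}

#' Compute the evaluation metric suite
#'
#' AUROC is the Mann-Whitney probability that a random positive outscores a
#' random negative, ties counted one half. AUPR is the non-interpolated
#' precision-recall step integral. F1, precision, recall and accuracy are
#' computed at `threshold` (precision defined as 0 when nothing is predicted
#' positive). With a single class present, the rank metrics are `NA` and a
#' classed warning (`tcrbench_single_class`) is raised; thresholded metrics
#' are still returned.
#'
#' @param labels Binary vector (1 = positive).
#' @param scores Numeric scores, same length.
#' @param threshold Classification threshold (default 0.5).
#' @return A list of class `eval_report`.
#' @examples
#' compute_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))$auroc  # 0.75
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) {
    tb_stop("tcrbench_config_error", "labels and scores differ in length")
  }
  if (!length(labels)) {
    tb_stop("tcrbench_empty_list", "nothing to evaluate")
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    tb_warn("tcrbench_single_class",
            "only one class present; AUROC/AUPR are NA")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (n1 == 0L) 0 else tp / n1
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  structure(list(
    auroc = auroc_mw(labels, scores),
    aupr = aupr_step(labels, scores),
    f1 = f1, precision = precision, recall = recall,
    accuracy = (tp + tn) / length(labels),
    n_pos = n1, n_neg = n0, threshold = threshold
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n = %d (%d pos / %d neg), threshold %.2f\n  AUROC %.4f | AUPR %.4f | F1 %.4f | prec %.4f | rec %.4f | acc %.4f\n",
    x$n_pos + x$n_neg, x$n_pos, x$n_neg, x$threshold,
    x$auroc, x$aupr, x$f1, x$precision, x$recall, x$accuracy))
  invisible(x)
}

#' Per-peptide test AUROC
#'
#' Computes AUROC within each test peptide's rows. Peptides whose rows carry
#' a single class have no within-peptide ranking problem; their AUROC is `NA`
#' and they must be excluded from averages (the returned counts make that
#' auditable). Note the global AUROC also ranks *across* peptides, so it is
#' not a weighted mean of these values.
#'
#' @param test A [sample_table()] of test rows.
#' @param scores Numeric scores aligned to `test` rows.
#' @return Data frame with columns `peptide`, `auroc`, `n_pos`, `n_neg`,
#'   sorted by total count descending.
#' @export
peptide_specific_auroc <- function(test, scores) {
  stopifnot(nrow(test) == length(scores))
  peps <- unique(test$peptide)
  rows <- split(seq_len(nrow(test)), test$peptide)[peps]
  out <- data.frame(
    peptide = peps,
    auroc = vapply(rows, function(i) auroc_mw(test$label[i], scores[i]),
                   numeric(1)),
    n_pos = vapply(rows, function(i) sum(test$label[i] == 1L), integer(1)),
    n_neg = vapply(rows, function(i) sum(test$label[i] == 0L), integer(1))
  )
  out <- out[order(-(out$n_pos + out$n_neg)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate metric reports over repeated splits
#'
#' Arithmetic mean and population standard deviation of each metric over `k`
#' independent train/test splits (`k` is recorded so the sample standard
#' deviation can be recovered).
#'
#' @param reports A list of `eval_report`s from [compute_metrics()].
#' @return A list of class `aggregate_report`: per-metric `mean` and `sd`
#'   vectors plus `k`.
#' @export
aggregate_over_splits <- function(reports) {
  if (!length(reports)) {
    tb_stop("tcrbench_empty_list", "no reports to aggregate")
  }
  metrics <- c("auroc", "aupr", "f1", "precision", "recall", "accuracy")
  vals <- sapply(metrics, function(m)
    vapply(reports, function(r) as.numeric(r[[m]]), numeric(1)))
  vals <- matrix(vals, nrow = length(reports),
                 dimnames = list(NULL, metrics))
  k <- length(reports)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(list(mean = colMeans(vals),
                 sd = apply(vals, 2, pop_sd),
                 k = k),
            class = "aggregate_report")
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat(sprintf("<aggregate_report> over %d splits (mean +/- population sd)\n", x$k))
  for (m in names(x$mean)) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}
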