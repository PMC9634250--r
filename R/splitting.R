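# Random split (RS) and peptide-wise hard split (HS), with audits.

#' Hard-split settings
#'
#' The hard split holds out whole peptides: test peptides are sampled from
#' `P_{l,u}`, the set of peptides observed in at least `l` and at most `u`
#' tuples. `l` guarantees held-out peptides pair with a broad variety of
#' CDR3s; `u` stops a single frequent peptide from saturating the test
#' budget. `min_test_frac` is a *minimum* — the loop stops at the first
#' peptide that fills the budget, so the achieved fraction may exceed it.
#' Defaults follow the standard (peptide, CDR3beta) protocol
#' (85/15 minimum ratio, `l = 500`, `u = 10000`); for the paired-chain + MHC
#' setting use `l = 100`, `u = 5000`.
#'
#' @param min_test_frac Minimum test fraction (default 0.15).
#' @param l,u Inclusive per-peptide tuple-count bounds defining `P_{l,u}`.
#' @param seed Integer RNG seed for peptide sampling.
#' @return A `hard_split_config` list.
#' @export
hard_split_config <- function(min_test_frac = 0.15, l = 500L, u = 10000L,
                              seed = 1L) {
  if (min_test_frac <= 0 || min_test_frac >= 1) {
    tb_stop("tcrbench_config_error", "min_test_frac must be in (0, 1)")
  }
  if (l < 1L || l > u) {
    tb_stop("tcrbench_config_error", "need 1 <= l <= u")
  }
  structure(list(min_test_frac = min_test_frac, l = as.integer(l),
                 u = as.numeric(u), seed = as.integer(seed)),
            class = "hard_split_config")
}

new_split_result <- function(train, test, method, test_peptides = character(0),
                             config = NULL, seed = NA_integer_,
                             underfilled = FALSE, n = NA_integer_) {
  structure(list(train_indices = as.integer(train),
                 test_indices = as.integer(test),
                 test_peptides = test_peptides,
                 method = method, config = config, seed = seed,
                 underfilled = underfilled, n = as.integer(n)),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %s: %d train / %d test (%.1f%% test)%s\n",
              x$method, length(x$train_indices), length(x$test_indices),
              100 * length(x$test_indices) / max(1L, x$n),
              if (isTRUE(x$underfilled)) " [underfilled]" else ""))
  if (length(x$test_peptides)) {
    cat(sprintf("  held-out peptides (%d): %s\n", length(x$test_peptides),
                paste(utils::head(x$test_peptides, 5), collapse = ", ")))
  }
  invisible(x)
}

#' Random train/test split
#'
#' Samples `round(test_frac * nrow(table))` test rows uniformly without
#' replacement; the rest form the training set. Deterministic given `seed`.
#'
#' @param table A [sample_table()].
#' @param test_frac Test fraction (default 0.2, i.e. an 80/20 split).
#' @param seed Integer RNG seed.
#' @return A `split_result` with `method = "RS"`.
#' @export
random_split <- function(table, test_frac = 0.2, seed = 1L) {
  n <- nrow(table)
  if (n < 2L) tb_stop("tcrbench_config_error", "need at least 2 rows to split")
  n_test <- round(test_frac * n)
  if (n_test < 1L || n_test >= n) {
    tb_stop("tcrbench_config_error",
            sprintf("test_frac = %g yields an empty train or test set", test_frac))
  }
  test <- with_seed(seed, sample.int(n, n_test))
  test <- sort(test)
  new_split_result(setdiff(seq_len(n), test), test, "RS",
                   config = list(test_frac = test_frac), seed = seed, n = n)
}

#' Peptides eligible for hard-split test sets
#'
#' Returns `P_{l,u}`: the peptides observed in at least `l` and at most `u`
#' rows of `table` (which should already be deduplicated for its setting).
#'
#' @param table A [sample_table()].
#' @param l,u Inclusive tuple-count bounds.
#' @return Character vector of eligible peptides, lexicographically sorted.
#' @export
eligible_test_peptides <- function(table, l = 500L, u = 10000L) {
  counts <- table(table$peptide)
  sort(names(counts)[counts >= l & counts <= u])
}

#' Peptide-wise hard train/test split
#'
#' Samples peptides uniformly without replacement from `P_{l,u}`; all rows of
#' a sampled peptide go to the test set; sampling repeats until the test set
#' reaches `min_test_frac` of the rows (a minimum, so the final test set can
#' overshoot). Guarantees that no peptide occurs on both sides. If `P_{l,u}`
#' is exhausted before the budget is met, the accumulated test set is
#' returned with `underfilled = TRUE`.
#'
#' @param table A deduplicated [sample_table()].
#' @param cfg A [hard_split_config()].
#' @return A `split_result` with `method = "HS"` and the held-out peptides.
#' @export
hard_split <- function(table, cfg = hard_split_config()) {
  n <- nrow(table)
  eligible <- eligible_test_peptides(table, cfg$l, cfg$u)
  if (!length(eligible)) {
    tb_stop("tcrbench_no_eligible_peptides",
            sprintf("no peptide occurs between %d and %g times", cfg$l, cfg$u))
  }
  # materialized in lexicographic order, then seeded shuffle => reproducible
  order_out <- with_seed(cfg$seed, sample(eligible))
  budget <- cfg$min_test_frac * n
  pep_rows <- split(seq_len(n), table$peptide)
  test <- integer(0)
  taken <- character(0)
  for (p in order_out) {
    test <- c(test, pep_rows[[p]])
    taken <- c(taken, p)
    if (length(test) >= budget) break
  }
  underfilled <- length(test) < budget
  test <- sort(test)
  new_split_result(setdiff(seq_len(n), test), test, "HS",
                   test_peptides = taken, config = cfg, seed = cfg$seed,
                   underfilled = underfilled, n = n)
}

#' Audit a train/test split for peptide leakage
#'
#' Reports (a) the number of peptides shared between train and test — the
#' hard-split guarantee is that this is zero; (b) shared CDR3beta/CDR3alpha
#' sequence counts (informational: TCRs *are* allowed to recur across sides);
#' (c) the achieved test fraction; and (d) per-test-peptide positive/negative
#' counts.
#'
#' @param table The [sample_table()] that was split.
#' @param split A `split_result` from [random_split()] or [hard_split()].
#' @return A list of class `split_audit`.
#' @export
audit_split <- function(table, split) {
  n <- nrow(table)
  idx <- c(split$train_indices, split$test_indices)
  if (length(idx) != n || anyDuplicated(idx) || any(idx < 1L | idx > n)) {
    tb_stop("tcrbench_index_error",
            "split indices are not a partition of the table rows")
  }
  tr <- table[split$train_indices, , drop = FALSE]
  te <- table[split$test_indices, , drop = FALSE]
  shared <- function(col) {
    a <- unique(tr[[col]][nzchar(tr[[col]])])
    b <- unique(te[[col]][nzchar(te[[col]])])
    length(intersect(a, b))
  }
  per_pep <- if (nrow(te)) {
    agg <- stats::aggregate(cbind(pos = te$label == 1L, neg = te$label == 0L),
                            by = list(peptide = te$peptide), FUN = sum)
    agg[order(-(agg$pos + agg$neg)), , drop = FALSE]
  } else {
    data.frame(peptide = character(0), pos = integer(0), neg = integer(0))
  }
  rownames(per_pep) <- NULL
  structure(list(
    method = split$method,
    shared_peptides = shared("peptide"),
    shared_cdr3b = shared("cdr3b"),
    shared_cdr3a = shared("cdr3a"),
    test_fraction = nrow(te) / n,
    n_train = nrow(tr), n_test = nrow(te),
    per_test_peptide = per_pep
  ), class = "split_audit")
}

#' @export
print.split_audit <- function(x, ...) {
  cat(sprintf("<split_audit> %s: test fraction %.3f (%d/%d rows)\n",
              x$method, x$test_fraction, x$n_test, x$n_train + x$n_test))
  cat(sprintf("  shared peptides: %d | shared CDR3b: %d | shared CDR3a: %d\n",
              x$shared_peptides, x$shared_cdr3b, x$shared_cdr3a))
  cat(sprintf("  test peptides: %d\n", nrow(x$per_test_peptide)))
  invisible(x)
}
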