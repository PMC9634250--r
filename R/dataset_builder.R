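# Benchmark assembly: length filtration, per-setting deduplication,
# randomized-recombination (RN) negative generation.

#' Length-filtration bounds
#'
#' Default bounds keep peptides shorter than 16 residues, CDR3alpha between 7
#' and 21 (inclusive) and CDR3beta between 9 and 23 (inclusive); tuples with
#' consistently longer chains are excluded so downstream padded encodings
#' stay small.
#'
#' @param peptide_max Exclusive upper bound on peptide length.
#' @param cdr3a_min,cdr3a_max Inclusive CDR3alpha length bounds.
#' @param cdr3b_min,cdr3b_max Inclusive CDR3beta length bounds.
#' @return A `length_filter_config` list.
#' @export
length_filter_config <- function(peptide_max = 16L, cdr3a_min = 7L,
                                 cdr3a_max = 21L, cdr3b_min = 9L,
                                 cdr3b_max = 23L) {
  cfg <- list(peptide_max = as.integer(peptide_max),
              cdr3a_min = as.integer(cdr3a_min),
              cdr3a_max = as.integer(cdr3a_max),
              cdr3b_min = as.integer(cdr3b_min),
              cdr3b_max = as.integer(cdr3b_max))
  if (any(unlist(cfg) <= 0L) || cfg$cdr3a_min > cfg$cdr3a_max ||
      cfg$cdr3b_min > cfg$cdr3b_max) {
    tb_stop("tcrbench_config_error", "invalid length filter bounds")
  }
  structure(cfg, class = "length_filter_config")
}

#' RN (recombined-negative) generation settings
#'
#' @param ratio Negatives generated per positive (default 2).
#' @param seed Integer RNG seed.
#' @param pairing_mode `"joint"` (the whole CDR3/gene block is taken from one
#'   donor row, preserving real alpha/beta chain pairing) or `"independent"`
#'   (each chain block sampled from its own donor).
#' @return An `rn_config` list.
#' @export
rn_config <- function(ratio = 2, seed = 1L,
                      pairing_mode = c("joint", "independent")) {
  if (!is.numeric(ratio) || ratio <= 0) {
    tb_stop("tcrbench_config_error", "rn ratio must be > 0")
  }
  structure(list(ratio = ratio, seed = as.integer(seed),
                 pairing_mode = match.arg(pairing_mode)),
            class = "rn_config")
}

#' Filter samples by sequence length
#'
#' Keeps rows with `nchar(peptide) < peptide_max` and, when the chain is
#' present (non-empty), `cdr3a_min <= nchar(cdr3a) <= cdr3a_max` and
#' `cdr3b_min <= nchar(cdr3b) <= cdr3b_max`. Order-preserving and idempotent.
#'
#' @param table A [sample_table()].
#' @param cfg A [length_filter_config()].
#' @return The filtered `sample_table`; `attr(x, "n_length_filtered")` counts
#'   removed rows.
#' @export
filter_by_length <- function(table, cfg = length_filter_config()) {
  stopifnot(inherits(table, "sample_table"))
  lp <- nchar(table$peptide)
  lb <- nchar(table$cdr3b)
  la <- nchar(table$cdr3a)
  keep <- lp < cfg$peptide_max &
    lb >= cfg$cdr3b_min & lb <= cfg$cdr3b_max &
    (la == 0L | (la >= cfg$cdr3a_min & la <= cfg$cdr3a_max))
  out <- table[keep, , drop = FALSE]
  attr(out, "n_length_filtered") <- sum(!keep)
  out
}

#' Deduplicate samples under a tuple-identity setting
#'
#' Keeps the first occurrence of each (identity fields, label) key. Identity
#' keys observed with *both* labels are contradictory; they are handled per
#' `conflict_policy`: `"drop"` removes every row of the conflicting identity,
#' `"keep_positive"` keeps only its positive rows, `"keep_first"` keeps the
#' label seen first. Order-preserving and idempotent.
#'
#' @param table A [sample_table()].
#' @param setting Identity setting (defaults to the table's own).
#' @param conflict_policy See above.
#' @return Deduplicated `sample_table` with attributes `n_duplicates_removed`
#'   and `n_conflicts` (number of conflicting identity keys).
#' @export
deduplicate <- function(table, setting = tbl_setting(table),
                        conflict_policy = c("drop", "keep_positive",
                                            "keep_first")) {
  stopifnot(inherits(table, "sample_table"))
  conflict_policy <- match.arg(conflict_policy)
  setting <- setting(setting)
  id <- identity_key(table, setting)
  idl <- paste(id, table$label, sep = "\r")
  keep <- !duplicated(idl)
  n_dup <- sum(!keep)
  pos_ids <- unique(id[table$label == 1L])
  neg_ids <- unique(id[table$label == 0L])
  conflicted <- intersect(pos_ids, neg_ids)
  if (length(conflicted)) {
    in_conflict <- id %in% conflicted
    keep <- keep & switch(conflict_policy,
      drop = !in_conflict,
      keep_positive = !in_conflict | table$label == 1L,
      keep_first = {
        first_label <- table$label[match(id, id)]
        !in_conflict | table$label == first_label
      }
    )
  }
  out <- table[keep, , drop = FALSE]
  attr(out, "n_duplicates_removed") <- n_dup
  attr(out, "n_conflicts") <- length(conflicted)
  out
}

# CDR3/gene donor block used by RN recombination.
CDR3_BLOCK <- c("cdr3a", "cdr3b", "va", "ja", "vb", "db", "jb")

#' Generate recombined (RN) negatives from positive tuples
#'
#' Builds presumed-non-binding samples by re-pairing components of the
#' positive tuples: each candidate negative takes its peptide (together with
#' its MHC allele, i.e. the pMHC complex, when MHC is part of the identity)
#' from one donor positive and its CDR3/gene block from another. Candidates
#' that share the same `(peptide, cdr3b)` with any positive are discarded, as
#' are duplicates under the table's setting. Sampling is with replacement
#' over donors; total draws are capped at 50 times the target before a
#' shortfall is declared.
#'
#' @param positives A deduplicated [sample_table()] of label-1 rows.
#' @param cfg An [rn_config()].
#' @return A `sample_table` of `label = 0`, `negative_origin = "RN"` rows;
#'   attributes `rn_target` (requested count) and `rn_shortfall` (`TRUE` when
#'   fewer than `round(ratio * nrow(positives))` feasible negatives exist).
#' @export
generate_rn_negatives <- function(positives, cfg = rn_config()) {
  stopifnot(inherits(positives, "sample_table"))
  if (nrow(positives) == 0L) {
    tb_stop("tcrbench_empty_positives", "no positive samples to recombine")
  }
  if (any(positives$label != 1L)) {
    tb_stop("tcrbench_config_error",
            "generate_rn_negatives expects positives only (label = 1)")
  }
  st <- tbl_setting(positives)
  n_pos <- nrow(positives)
  target <- round(cfg$ratio * n_pos)
  pos_pair <- paste(positives$peptide, positives$cdr3b, sep = "\r")
  max_draws <- ceiling(50 * target)
  pep_block <- c("peptide", if ("mhc" %in% unclass(st)) "mhc")

  acc <- NULL
  seen <- character(0)
  drawn <- 0L
  with_seed(cfg$seed, {
    while (drawn < max_draws && (is.null(acc) || nrow(acc) < target)) {
      chunk <- min(max(2L * target, 1000L), max_draws - drawn)
      drawn <- drawn + chunk
      i <- sample.int(n_pos, chunk, replace = TRUE)
      cand <- positives[i, , drop = FALSE]
      if (cfg$pairing_mode == "joint") {
        j <- sample.int(n_pos, chunk, replace = TRUE)
        cand[CDR3_BLOCK] <- as.data.frame(positives)[j, CDR3_BLOCK]
      } else {
        ja <- sample.int(n_pos, chunk, replace = TRUE)
        jb <- sample.int(n_pos, chunk, replace = TRUE)
        a_cols <- c("cdr3a", "va", "ja")
        b_cols <- c("cdr3b", "vb", "db", "jb")
        cand[a_cols] <- as.data.frame(positives)[ja, a_cols]
        cand[b_cols] <- as.data.frame(positives)[jb, b_cols]
      }
      cand$label <- 0L
      cand$negative_origin <- "RN"
      cand$source <- "RN"
      pair <- paste(cand$peptide, cand$cdr3b, sep = "\r")
      idk <- identity_key(cand, st)
      ok <- !(pair %in% pos_pair) & !(idk %in% seen) & !duplicated(idk)
      cand <- cand[ok, , drop = FALSE]
      seen <- c(seen, idk[ok])
      acc <- if (is.null(acc)) cand else rbind(acc, cand)
    }
  })
  if (is.null(acc)) acc <- positives[0, , drop = FALSE]
  if (nrow(acc) > target) acc <- acc[seq_len(target), , drop = FALSE]
  out <- sample_table(as.data.frame(acc), setting = st, validate = FALSE)
  attr(out, "rn_target") <- target
  attr(out, "rn_shortfall") <- nrow(out) < target
  out
}

#' Assemble a benchmark dataset
#'
#' Runs the full pipeline in order: concatenate positives with any
#' assay-derived (NA) negatives, filter by length, deduplicate, generate RN
#' negatives from the filtered + deduplicated positives (when `rn_cfg` is
#' given), and deduplicate the final union. The `negative_origin` column
#' keeps the NA-only, RN-only and NA+RN negative subsets recoverable.
#'
#' @param positives `sample_table` of label-1 rows.
#' @param na_negatives Optional `sample_table` of assay negatives (label 0).
#' @param rn_cfg Optional [rn_config()]; omit to skip RN generation.
#' @param filter_cfg A [length_filter_config()].
#' @param setting Identity setting for deduplication.
#' @param conflict_policy Passed to [deduplicate()].
#' @param column_filter Optional `list(column =, min =)`: keep only rows whose
#'   numeric value in `column` is `>= min` (e.g. a database quality score).
#' @return The assembled `sample_table`; attributes `build_report` (a list of
#'   dropped/deduplicated/conflict/shortfall counts).
#' @export
assemble_dataset <- function(positives, na_negatives = NULL, rn_cfg = NULL,
                             filter_cfg = length_filter_config(),
                             setting = tbl_setting(positives),
                             conflict_policy = "drop",
                             column_filter = NULL) {
  setting <- setting(setting)
  tab <- as.data.frame(positives)
  if (!is.null(na_negatives)) {
    common <- intersect(names(tab), names(as.data.frame(na_negatives)))
    tab <- rbind(tab[common], as.data.frame(na_negatives)[common])
  }
  tab <- sample_table(tab, setting = setting, validate = FALSE)
  n_quality <- 0L
  if (!is.null(column_filter)) {
    v <- suppressWarnings(as.numeric(tab[[column_filter$column]]))
    keep <- !is.na(v) & v >= column_filter$min
    n_quality <- sum(!keep)
    tab <- tab[keep, , drop = FALSE]
  }
  tab <- filter_by_length(tab, filter_cfg)
  n_len <- attr(tab, "n_length_filtered")
  tab <- deduplicate(tab, setting, conflict_policy = conflict_policy)
  n_dup <- attr(tab, "n_duplicates_removed")
  n_conf <- attr(tab, "n_conflicts")
  shortfall <- FALSE
  if (!is.null(rn_cfg)) {
    pos <- tab[tab$label == 1L, , drop = FALSE]
    rn <- generate_rn_negatives(pos, rn_cfg)
    shortfall <- attr(rn, "rn_shortfall")
    tab <- sample_table(rbind(as.data.frame(tab), as.data.frame(rn)),
                        setting = setting, validate = FALSE)
    tab <- deduplicate(tab, setting, conflict_policy = "keep_first")
  }
  attr(tab, "build_report") <- list(
    n_quality_filtered = n_quality,
    n_length_filtered = n_len,
    n_duplicates_removed = n_dup,
    n_conflicts = n_conf,
    rn_shortfall = shortfall,
    n_pos = sum(tab$label == 1L),
    n_neg_na = sum(tab$negative_origin == "NA"),
    n_neg_rn = sum(tab$negative_origin == "RN")
  )
  tab
}
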