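# Seeded synthetic benchmark generator.
#
# Emulates the statistical structure that drives the leakage phenomena:
# heavy-tailed per-peptide tuple counts, class-disjoint CDR3 repertoires
# (NA_style), recombined negatives (RN_style, via the production RN code
# path), and ground-truth binding rules that are either peptide-idiosyncratic
# (non-transferable across peptides) or motif/compatibility-based
# (transferable).

#' Synthetic-dataset settings
#'
#' Defaults describe the standard generalization-failure scenario: 20
#' peptides with power-law (exponent 1.5) positive tuple counts clipped to
#' `[100, 400]` (so each peptide carries 300-1200 tuples once RN negatives
#' at ratio 2 are added), a pool of 3000 unique CDR3beta sequences, and a
#' peptide-idiosyncratic binding rule. Sequence length ranges sit inside the
#' dataset builder's filter bounds so no generated row is ever filtered out.
#'
#' @param n_peptides Number of distinct peptides.
#' @param count_range Min/max positive tuples per peptide (power-law clip).
#' @param count_exponent Power-law exponent of per-peptide counts.
#' @param n_cdr3_pool Number of unique CDR3beta sequences in the pool.
#' @param cdr3_length_range,peptide_length_range Inclusive length ranges.
#' @param binding_rule `"idiosyncratic"` (each peptide carries an independent
#'   random predicate over CDR3 features; nothing transfers to unseen
#'   peptides) or `"motif"` (a single global peptide-CDR3 residue-class
#'   compatibility rule; transfers across peptides). For the motif rule a
#'   wide peptide panel with high CDR3 reuse (e.g. `n_peptides = 300`,
#'   `count_range = c(35, 100)`, `n_cdr3_pool = 600`) is needed before the
#'   anchor positions become statistically identifiable from training
#'   peptides; see the methods vignette.
#' @param motif_strength Fraction of positive rows satisfying the motif rule
#'   (rest are corrupted); motif rule only.
#' @param negative_mode `"RN_style"` (recombined negatives via
#'   [generate_rn_negatives()]) or `"NA_style"` (negative CDR3s drawn from a
#'   pool disjoint from the positive pool, emulating assay negatives).
#' @param rn_ratio Negatives per positive (default 2).
#' @param with_alpha_mhc Also generate paired CDR3alpha and an MHC allele
#'   (4-field setting).
#' @param seed Master seed; everything downstream is derived from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_peptides = 20L, count_range = c(100L, 400L),
                         count_exponent = 1.5, n_cdr3_pool = 3000L,
                         cdr3_length_range = c(12L, 16L),
                         peptide_length_range = c(8L, 12L),
                         binding_rule = c("idiosyncratic", "motif"),
                         motif_strength = 0.9,
                         negative_mode = c("RN_style", "NA_style"),
                         rn_ratio = 2, with_alpha_mhc = FALSE, seed = 1L) {
  binding_rule <- match.arg(binding_rule)
  negative_mode <- match.arg(negative_mode)
  if (n_peptides < 1L || n_cdr3_pool < 1L || any(count_range < 1L) ||
      count_range[1] > count_range[2]) {
    tb_stop("tcrbench_config_error", "counts and pool sizes must be positive")
  }
  if (cdr3_length_range[1] < 9L || cdr3_length_range[2] > 23L ||
      peptide_length_range[1] < 1L || peptide_length_range[2] > 15L) {
    tb_stop("tcrbench_config_error",
            "length ranges must sit inside the builder filter bounds")
  }
  if (motif_strength < 0 || motif_strength > 1) {
    tb_stop("tcrbench_config_error", "motif_strength must be in [0, 1]")
  }
  structure(list(n_peptides = as.integer(n_peptides),
                 count_range = as.integer(count_range),
                 count_exponent = count_exponent,
                 n_cdr3_pool = as.integer(n_cdr3_pool),
                 cdr3_length_range = as.integer(cdr3_length_range),
                 peptide_length_range = as.integer(peptide_length_range),
                 binding_rule = binding_rule,
                 motif_strength = motif_strength,
                 negative_mode = negative_mode,
                 rn_ratio = rn_ratio,
                 with_alpha_mhc = isTRUE(with_alpha_mhc),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# n unique uniform-random sequences over the 20-letter alphabet.
gen_unique_seqs <- function(n, len_range, exclude = character(0)) {
  out <- character(0)
  for (round in 1:50) {
    need <- n - length(out)
    if (need <= 0L) break
    lens <- sample(seq(len_range[1], len_range[2]), need, replace = TRUE)
    fresh <- vapply(lens, function(l)
      paste(sample(AA20, l, replace = TRUE), collapse = ""), character(1))
    out <- unique(c(out, setdiff(fresh, exclude)))
  }
  if (length(out) < n) {
    tb_stop("tcrbench_config_error", "sequence space too small for pool size")
  }
  out[seq_len(n)]
}

# Power-law sample clipped to [xmin, xmax] via inverse CDF.
rpowerlaw <- function(n, xmin, xmax, alpha) {
  if (xmin == xmax) return(rep(as.integer(xmin), n))
  u <- stats::runif(n)
  a1 <- 1 - alpha
  x <- ((xmax^a1 - xmin^a1) * u + xmin^a1)^(1 / a1)
  pmin(pmax(as.integer(round(x)), as.integer(xmin)), as.integer(xmax))
}

#' Generate a synthetic peptide repertoire and CDR3 pool
#'
#' Per-peptide target positive counts follow the configured clipped power
#' law (heavy-tailed, like real epitope databases where one peptide pairs
#' with thousands of TCRs); sequences are unique uniform-random strings over
#' the 20-letter alphabet. Deterministic given `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return A list: `peptides` (character), `counts` (target positive tuples
#'   per peptide), `cdr3_pool` (character).
#' @export
generate_repertoire <- function(cfg = synth_config()) {
  if (cfg$n_cdr3_pool < cfg$count_range[2]) {
    tb_stop("tcrbench_config_error",
            "n_cdr3_pool is smaller than the maximum per-peptide count")
  }
  with_seed(cfg$seed, {
    counts <- rpowerlaw(cfg$n_peptides, cfg$count_range[1],
                        cfg$count_range[2], cfg$count_exponent)
    peptides <- gen_unique_seqs(cfg$n_peptides, cfg$peptide_length_range)
    cdr3_pool <- gen_unique_seqs(cfg$n_cdr3_pool, cfg$cdr3_length_range)
    list(peptides = peptides, counts = counts, cdr3_pool = cdr3_pool)
  })
}

# ---- ground-truth binding rules -------------------------------------------

new_idio_rule <- function(seed, anchor_max, subset_size = 4L) {
  # one shared CDR3 contact site; what it must contain is peptide-specific
  anchor_pos <- with_seed(seed, sample.int(anchor_max, 1))
  structure(list(type = "idiosyncratic", seed = seed,
                 anchor_pos = anchor_pos,
                 subset_size = as.integer(subset_size)),
            class = "binding_rule")
}

# Global compatibility rule: residues fall into n_groups classes (think
# complementary chemistry); a CDR3 binds a peptide iff the classes at one
# fixed contact-position pair agree. The class map and positions are global,
# so what is learned on training peptides applies to unseen ones.
new_motif_rule <- function(seed, pep_min_len, cdr3_min_len, n_groups = 4L) {
  with_seed(seed, {
    groups <- stats::setNames(sample(rep(seq_len(n_groups), 20 %/% n_groups)),
                              AA20)
    pep_anchor <- sample.int(pep_min_len, 1)
    cdr3_core <- sample.int(cdr3_min_len, 1)
  })
  structure(list(type = "motif", seed = seed, groups = groups,
                 pep_anchor = pep_anchor, cdr3_core = cdr3_core,
                 n_groups = n_groups),
            class = "binding_rule")
}

# Per-peptide predicate parameters (idiosyncratic rule): the accepted
# residue subset at the shared contact site, derived by hashing the peptide.
idio_params <- function(rule, peptide) {
  list(pos = rule$anchor_pos,
       accept = with_seed(str_hash(peptide, rule$seed),
                          sample(AA20, rule$subset_size)))
}

#' Evaluate the ground-truth binding rule
#'
#' Returns the true binding indicator for each (peptide, CDR3beta) pair.
#' Under the idiosyncratic rule all peptides read the same CDR3 contact
#' site, but each peptide accepts its own seeded random residue subset
#' there — deterministic within a peptide, independent across peptides;
#' under the motif rule a single global residue-class map links one fixed
#' peptide anchor position to one fixed CDR3 core position: the pair binds
#' iff the two classes agree.
#'
#' @param rule A `binding_rule` returned by [generate_dataset()].
#' @param peptides,cdr3s Character vectors of equal length.
#' @return Logical vector: does the pair bind under the ground truth?
#' @export
rule_match <- function(rule, peptides, cdr3s) {
  stopifnot(length(peptides) == length(cdr3s))
  if (rule$type == "idiosyncratic") {
    out <- logical(length(peptides))
    for (p in unique(peptides)) {
      par <- idio_params(rule, p)
      i <- peptides == p
      out[i] <- substr(cdr3s[i], par$pos, par$pos) %in% par$accept
    }
    out
  } else {
    gp <- rule$groups[substr(peptides, rule$pep_anchor, rule$pep_anchor)]
    gc <- rule$groups[substr(cdr3s, rule$cdr3_core, rule$cdr3_core)]
    unname(gp == gc)
  }
}

#' Bayes-rule scores for a table under the ground truth
#'
#' Convenience wrapper: the ground-truth binding indicator as a numeric
#' score, i.e. the best any classifier could do given full knowledge of the
#' rule. On held-out peptides under the idiosyncratic rule this scorer —
#' like every scorer that has not seen the peptide's predicate — hovers at
#' AUROC 0.5 against recombined negatives.
#'
#' @param rule A `binding_rule`.
#' @param table A [sample_table()].
#' @return Numeric scores (0/1), one per row.
#' @export
bayes_scores <- function(rule, table) {
  as.numeric(rule_match(rule, table$peptide, table$cdr3b))
}

# ---- dataset generation ----------------------------------------------------

sample_positive_cdr3s <- function(pool, fires, n_target, strength) {
  hit <- pool[fires]
  miss <- pool[!fires]
  n_hit <- round(strength * n_target)
  n_miss <- n_target - n_hit
  if (length(hit) < n_hit || length(miss) < n_miss) {
    tb_stop("tcrbench_config_error",
            sprintf("CDR3 pool cannot supply %d matching + %d non-matching sequences",
                    n_hit, n_miss))
  }
  c(if (n_hit) sample(hit, n_hit),
    if (n_miss) sample(miss, n_miss))
}

#' Generate a seeded synthetic benchmark dataset
#'
#' Builds positives per peptide according to the ground-truth binding rule,
#' then negatives per `cfg$negative_mode`:
#' * `RN_style` re-pairs components of the positive tuples through the
#'   production [generate_rn_negatives()] code path and labels every
#'   recombination 0 — recombined pairs are *presumed* non-binding, exactly
#'   the assumption real RN sets make;
#' * `NA_style` draws negative CDR3s from a pool disjoint from the positive
#'   pool, reproducing the fully class-disjoint CDR3 repertoires of
#'   assay-derived negative sets.
#'
#' Under the idiosyncratic rule, positives are the CDR3s firing the
#' peptide's own random predicate; under the motif rule a fraction
#' `motif_strength` of each peptide's positives satisfies the global
#' compatibility rule and the rest are corruptions.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `synth_dataset`: `table` (a [sample_table()]),
#'   `rule` (the ground truth, see [rule_match()]), and `repertoire`.
#' @export
generate_dataset <- function(cfg = synth_config()) {
  seeds <- with_seed(cfg$seed, sample.int(2147483646L, 6L))
  rp <- generate_repertoire(cfg)
  rule <- if (cfg$binding_rule == "idiosyncratic") {
    new_idio_rule(seeds[2], anchor_max = cfg$cdr3_length_range[1])
  } else {
    new_motif_rule(seeds[2], pep_min_len = cfg$peptide_length_range[1],
                   cdr3_min_len = cfg$cdr3_length_range[1])
  }

  pos <- with_seed(seeds[3], {
    rows <- lapply(seq_along(rp$peptides), function(i) {
      p <- rp$peptides[i]
      fires <- rule_match(rule, rep(p, length(rp$cdr3_pool)), rp$cdr3_pool)
      strength <- if (cfg$binding_rule == "motif") cfg$motif_strength else 1
      cdr3 <- sample_positive_cdr3s(rp$cdr3_pool, fires, rp$counts[i],
                                    strength)
      data.frame(peptide = p, cdr3b = cdr3, label = 1L,
                 source = "synthetic", stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  st <- "pep_cdr3b"
  if (cfg$with_alpha_mhc) {
    st <- "paired_mhc"
    with_seed(seeds[6], {
      alpha_pool <- gen_unique_seqs(cfg$n_cdr3_pool, c(7L, 21L),
                                    exclude = rp$cdr3_pool)
      alleles <- paste0("HLA-", sprintf("%02d", seq_len(6)))
      pep_allele <- stats::setNames(sample(alleles, cfg$n_peptides,
                                           replace = TRUE), rp$peptides)
    })
    # fixed alpha partner per beta chain: preserves real chain pairing
    pos$cdr3a <- alpha_pool[match(pos$cdr3b, rp$cdr3_pool)]
    pos$mhc <- unname(pep_allele[pos$peptide])
  }
  pos_tab <- sample_table(pos, setting = st, validate = FALSE)

  neg_tab <- if (cfg$negative_mode == "RN_style") {
    generate_rn_negatives(pos_tab, rn_config(ratio = cfg$rn_ratio,
                                             seed = seeds[4]))
  } else {
    with_seed(seeds[5], {
      neg_pool <- gen_unique_seqs(cfg$n_cdr3_pool, cfg$cdr3_length_range,
                                  exclude = rp$cdr3_pool)
      rows <- lapply(seq_along(rp$peptides), function(i) {
        n_neg <- round(cfg$rn_ratio * rp$counts[i])
        if (n_neg > length(neg_pool)) {
          tb_stop("tcrbench_config_error",
                  "negative CDR3 pool smaller than the per-peptide negative budget")
        }
        data.frame(peptide = rp$peptides[i],
                   cdr3b = sample(neg_pool, n_neg), label = 0L,
                   source = "synthetic", negative_origin = "NA",
                   stringsAsFactors = FALSE)
      })
      neg <- do.call(rbind, rows)
      if (cfg$with_alpha_mhc) {
        alpha_neg <- gen_unique_seqs(cfg$n_cdr3_pool, c(7L, 21L),
                                     exclude = c(rp$cdr3_pool, alpha_pool))
        neg$cdr3a <- alpha_neg[match(neg$cdr3b, neg_pool)]
        neg$mhc <- unname(pep_allele[neg$peptide])
      }
      sample_table(neg, setting = st, validate = FALSE)
    })
  }

  tab <- sample_table(rbind(as.data.frame(pos_tab), as.data.frame(neg_tab)),
                      setting = st, validate = FALSE)
  structure(list(table = tab, rule = rule, repertoire = rp, config = cfg),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf(
    "<synth_dataset> %d rows (%d pos / %d neg), %d peptides; rule: %s; negatives: %s; seed %d\n",
    nrow(x$table), sum(x$table$label == 1L), sum(x$table$label == 0L),
    x$config$n_peptides, x$config$binding_rule, x$config$negative_mode,
    x$config$seed))
  invisible(x)
}
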