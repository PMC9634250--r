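small_cfg <- function(..., seed = 5) {
  synth_config(n_peptides = 8, count_range = c(20, 50), n_cdr3_pool = 400,
               seed = seed, ...)
}

test_that("repertoires respect the configured counts, lengths and uniqueness", {
  rp <- generate_repertoire(small_cfg())
  expect_length(rp$peptides, 8)
  expect_false(any(duplicated(rp$peptides)))
  expect_false(any(duplicated(rp$cdr3_pool)))
  expect_true(all(rp$counts >= 20 & rp$counts <= 50))
  expect_true(all(nchar(rp$peptides) >= 8 & nchar(rp$peptides) <= 12))
  expect_true(all(nchar(rp$cdr3_pool) >= 12 & nchar(rp$cdr3_pool) <= 16))

  # deterministic per seed
  expect_identical(rp, generate_repertoire(small_cfg()))
  expect_error(generate_repertoire(synth_config(n_cdr3_pool = 30,
                                                count_range = c(20, 50))),
               class = "tcrbench_config_error")
  expect_error(synth_config(cdr3_length_range = c(5, 16)),
               class = "tcrbench_config_error")
  expect_error(synth_config(motif_strength = 1.2),
               class = "tcrbench_config_error")
})

test_that("peptides built for the standard hard-split band are all eligible", {
  cfg <- synth_config(n_peptides = 10, count_range = c(500, 10000),
                      count_exponent = 1.5, n_cdr3_pool = 15000, seed = 2)
  rp <- generate_repertoire(cfg)
  expect_true(all(rp$counts >= 500 & rp$counts <= 10000))
})

test_that("generated datasets are seed-deterministic end to end", {
  d1 <- generate_dataset(small_cfg())
  d2 <- generate_dataset(small_cfg())
  expect_identical(as.data.frame(d1$table), as.data.frame(d2$table))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_samples(d1$table, p1); write_samples(d2$table, p2)
  expect_identical(readLines(p1), readLines(p2))
  d3 <- generate_dataset(small_cfg(seed = 6))
  expect_false(identical(as.data.frame(d1$table), as.data.frame(d3$table)))
})

test_that("generated tables pass the builder filters with zero drops", {
  for (cfg in list(small_cfg(), small_cfg(binding_rule = "motif"),
                   small_cfg(negative_mode = "NA_style"))) {
    tab <- generate_dataset(cfg)$table
    out <- filter_by_length(tab)
    expect_identical(attr(out, "n_length_filtered"), 0L)
    expect_identical(nrow(deduplicate(tab)), nrow(tab))
  }
})

test_that("RN-style output hits the 2x ratio and reuses the positive pool", {
  ds <- generate_dataset(small_cfg())
  tab <- ds$table
  n_pos <- sum(tab$label == 1L)
  n_neg <- sum(tab$label == 0L)
  expect_identical(n_neg, as.integer(round(2 * n_pos)))
  expect_true(all(tab$negative_origin[tab$label == 0L] == "RN"))
  expect_true(all(tab$cdr3b[tab$label == 0L] %in% tab$cdr3b[tab$label == 1L]))
})

test_that("NA-style output draws negatives from a disjoint CDR3 pool", {
  ds <- generate_dataset(small_cfg(negative_mode = "NA_style"))
  tab <- ds$table
  expect_identical(sum(tab$label == 0L), as.integer(round(2 * sum(tab$label == 1L))))
  expect_true(all(tab$negative_origin[tab$label == 0L] == "NA"))
  expect_length(intersect(tab$cdr3b[tab$label == 1L],
                          tab$cdr3b[tab$label == 0L]), 0)
})

test_that("the idiosyncratic ground truth is deterministic per peptide, independent across", {
  ds <- generate_dataset(small_cfg())
  rule <- ds$rule
  rp <- ds$repertoire
  m1 <- rule_match(rule, rep(rp$peptides[1], 400), rp$cdr3_pool)
  expect_identical(m1, rule_match(rule, rep(rp$peptides[1], 400), rp$cdr3_pool))
  # every generated positive satisfies its peptide's predicate
  pos <- ds$table[ds$table$label == 1L, ]
  expect_true(all(rule_match(rule, pos$peptide, pos$cdr3b)))
  # predicates differ between peptides (probabilistic but overwhelming)
  others <- sapply(rp$peptides[-1], function(p)
    mean(m1 == rule_match(rule, rep(p, 400), rp$cdr3_pool)))
  expect_true(any(others < 0.95))
})

test_that("the motif ground truth depends only on the global residue classes", {
  ds <- generate_dataset(small_cfg(binding_rule = "motif"))
  rule <- ds$rule
  # two peptides sharing the anchor-position residue have identical match sets
  p1 <- "ACDEFGHI"; p2 <- "KLMNPQRS"
  substr(p2, rule$pep_anchor, rule$pep_anchor) <-
    substr(p1, rule$pep_anchor, rule$pep_anchor)
  cdrs <- ds$repertoire$cdr3_pool[1:200]
  expect_identical(rule_match(rule, rep(p1, 200), cdrs),
                   rule_match(rule, rep(p2, 200), cdrs))
  # positives honour the configured strength
  pos <- ds$table[ds$table$label == 1L, ]
  expect_equal(mean(rule_match(rule, pos$peptide, pos$cdr3b)), 0.9,
               tolerance = 0.03)
})

test_that("no scorer ignorant of a held-out peptide's predicate beats chance", {
  ds <- generate_dataset(small_cfg(seed = 11))
  tab <- ds$table
  p_star <- ds$repertoire$peptides[1]
  rows <- tab[tab$peptide == p_star, ]
  # foreign predicates: the same rule family under independent seeds
  aucs <- sapply(1:5, function(s) {
    foreign <- tcrbench:::new_idio_rule(1000 + s,
                                        anchor_max = 12L)
    compute_metrics(rows$label,
                    as.numeric(rule_match(foreign, rows$peptide,
                                          rows$cdr3b)))$auroc
  })
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("paired-chain generation fixes the alpha partner and the peptide's allele", {
  ds <- generate_dataset(small_cfg(with_alpha_mhc = TRUE))
  tab <- ds$table
  expect_identical(unclass(attr(tab, "setting")),
                   c("peptide", "cdr3b", "cdr3a", "mhc"))
  expect_true(all(nzchar(tab$cdr3a)))
  expect_true(all(nzchar(tab$mhc)))
  # one alpha partner per beta chain (pairing preserved through recombination)
  expect_true(all(tapply(tab$cdr3a, tab$cdr3b,
                         function(x) length(unique(x))) == 1L))
  # one allele per peptide
  expect_true(all(tapply(tab$mhc, tab$peptide,
                         function(x) length(unique(x))) == 1L))
})
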