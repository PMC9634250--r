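test_that("length filtration keeps exactly the in-bounds rows, in order", {
  # 6 rows crossing peptide lengths {9, 15, 16} x cdr3b lengths {8, 9, 23, 24}
  pep <- c(strrep("A", 9), strrep("A", 15), strrep("A", 16),
           strrep("G", 9), strrep("G", 15), strrep("G", 16))
  cdr <- c(strrep("C", 8), strrep("C", 9), strrep("C", 23),
           strrep("C", 24), strrep("C", 23), strrep("C", 9))
  tab <- make_table(pep, cdr, rep(1, 6))
  out <- filter_by_length(tab)
  # survivors by hand: row2 (15, 9), row5 (15, 23); all others violate a bound
  expect_identical(out$peptide, pep[c(2, 5)])
  expect_identical(out$cdr3b, cdr[c(2, 5)])
  expect_identical(attr(out, "n_length_filtered"), 4L)

  # peptide length 15 kept, 16 dropped (strict "< 16")
  expect_identical(nrow(filter_by_length(make_table(strrep("A", 15), strrep("C", 23), 1))), 1L)
  expect_identical(nrow(filter_by_length(make_table(strrep("A", 16), strrep("C", 23), 1))), 0L)

  # empty table, idempotence, missing cdr3a unconstrained
  expect_identical(nrow(filter_by_length(tab[0, ])), 0L)
  expect_identical(plain(filter_by_length(out)), plain(out))
})

test_that("cdr3a bounds apply only when the chain is present", {
  df <- data.frame(peptide = "NLVPMVATV", cdr3b = strrep("C", 12),
                   cdr3a = c("", strrep("A", 6), strrep("A", 7)), label = 1)
  tab <- sample_table(df, "pep_cdr3b")
  out <- filter_by_length(tab)
  expect_identical(out$cdr3a, c("", strrep("A", 7)))  # length-6 alpha dropped
})

test_that("deduplication keeps first occurrences and resolves label conflicts", {
  tab <- make_table(c("NLVPMVATV", "NLVPMVATV", "GILGFVFTL"),
                    c("CASSF" , "CASSF", "CASSF"), c(1, 1, 1))
  tab$source <- c("iedb", "vdjdb", "iedb")
  out <- deduplicate(tab)
  expect_identical(nrow(out), 2L)
  expect_identical(out$source[1], "iedb")  # first occurrence wins
  expect_identical(attr(out, "n_duplicates_removed"), 1L)

  # same identity with both labels
  con <- make_table(c("NLVPMVATV", "NLVPMVATV", "GILGFVFTL"),
                    c("CASSF", "CASSF", "CASSG"), c(1, 0, 1))
  dropped <- deduplicate(con, conflict_policy = "drop")
  expect_identical(dropped$peptide, "GILGFVFTL")
  expect_identical(attr(dropped, "n_conflicts"), 1L)
  keep_pos <- deduplicate(con, conflict_policy = "keep_positive")
  expect_identical(keep_pos$label, c(1L, 1L))
  keep_first <- deduplicate(con, conflict_policy = "keep_first")
  expect_identical(keep_first$label, c(1L, 1L))

  # idempotent; empty in, empty out
  expect_identical(plain(deduplicate(out)), plain(out))
  expect_identical(nrow(deduplicate(tab[0, ])), 0L)
})

test_that("deduplication widens with the setting", {
  df <- data.frame(peptide = "NLVPMVATV", cdr3b = "CASSIRSSYEQYF",
                   mhc = c("HLA-A", "HLA-B"), label = 1)
  tab <- sample_table(df, setting = c("peptide", "cdr3b", "mhc"))
  expect_identical(nrow(deduplicate(tab)), 2L)          # distinct under 3 fields
  expect_identical(nrow(deduplicate(tab, "pep_cdr3b")), 1L)
})

test_that("RN generation enumerates the feasible pool when the target exceeds it", {
  pos <- make_table(c("NLVPMVATV", "GILGFVFTL"), c("CASSIRSSF", "CASSQETQF"),
                    c(1, 1))
  rn <- generate_rn_negatives(pos, rn_config(ratio = 2, seed = 5))
  # brute force: of the 4 peptide x CDR3 combinations, 2 are positives;
  # the only feasible negatives are the 2 cross pairings
  got <- sort(paste(rn$peptide, rn$cdr3b))
  expect_identical(got, sort(c("NLVPMVATV CASSQETQF", "GILGFVFTL CASSIRSSF")))
  expect_true(attr(rn, "rn_shortfall"))
  expect_identical(attr(rn, "rn_target"), 4)
  expect_true(all(rn$label == 0L))
  expect_true(all(rn$negative_origin == "RN"))

  # single positive: no mismatched pair exists
  one <- generate_rn_negatives(pos[1, ], rn_config(2, 1))
  expect_identical(nrow(one), 0L)
  expect_true(attr(one, "rn_shortfall"))

  expect_error(generate_rn_negatives(pos[0, ], rn_config(2, 1)),
               class = "tcrbench_empty_positives")
  expect_error(generate_rn_negatives(make_table("ACD", "CASSFLYQ", 0)),
               class = "tcrbench_config_error")
})

test_that("RN generation hits the 2x target on ample pools, deterministically", {
  set.seed(42)
  pos <- make_table(
    paste0(replicate(100, paste(sample(LETTERS[c(1, 3, 4, 5, 7)], 9, TRUE),
                                collapse = ""))),
    replicate(100, paste(sample(c("C", "A", "S", "R", "Y"), 12, TRUE),
                         collapse = "")),
    rep(1, 100))
  pos <- deduplicate(pos)
  rn <- generate_rn_negatives(pos, rn_config(ratio = 2, seed = 7))
  expect_identical(nrow(rn), as.integer(round(2 * nrow(pos))))
  expect_false(attr(rn, "rn_shortfall"))
  # no (peptide, cdr3b) collision with positives; unique under the setting
  expect_length(intersect(paste(rn$peptide, rn$cdr3b),
                          paste(pos$peptide, pos$cdr3b)), 0)
  expect_false(any(duplicated(paste(rn$peptide, rn$cdr3b))))
  # recombination never invents sequences
  expect_true(all(rn$cdr3b %in% pos$cdr3b))
  expect_true(all(rn$peptide %in% pos$peptide))
  # bit-identical under the same seed
  rn2 <- generate_rn_negatives(pos, rn_config(ratio = 2, seed = 7))
  expect_identical(as.data.frame(rn), as.data.frame(rn2))
  expect_false(identical(as.data.frame(rn),
                         as.data.frame(generate_rn_negatives(pos, rn_config(2, 8)))))
})

test_that("joint pairing keeps donor chain blocks together", {
  df <- data.frame(peptide = c("NLVPMVATV", "GILGFVFTL", "ELAGIGILTV"),
                   cdr3b = c("CASSIRSSF", "CASSQETQF", "CASSLLGGF"),
                   cdr3a = c("CAVSDLF", "CAGNNRF", "CIVRAPF"),
                   mhc = "", label = 1)
  pos <- sample_table(df, "paired_mhc")
  rn <- generate_rn_negatives(pos, rn_config(ratio = 2, seed = 3))
  pairs <- paste(df$cdr3a, df$cdr3b)
  expect_true(all(paste(rn$cdr3a, rn$cdr3b) %in% pairs))
})

test_that("dataset assembly follows the pipeline order", {
  # one positive is removed by the length filter; the RN target must be
  # computed from the post-filter positive count
  pos <- make_table(c("NLVPMVATV", "GILGFVFTL", strrep("A", 16), "NLVPMVATV"),
                    c("CASSIRSSF", "CASSQETQF", "CASSLLGGF", "CASSIRSSF"),
                    rep(1, 4))
  na <- make_table("ELAGIGILTV", "CASSYYEQF", 0)
  out <- assemble_dataset(pos, na_negatives = na,
                          rn_cfg = rn_config(ratio = 2, seed = 9))
  rep_ <- attr(out, "build_report")
  expect_identical(rep_$n_length_filtered, 1L)
  expect_identical(rep_$n_duplicates_removed, 1L)
  expect_identical(rep_$n_pos, 2L)       # 4 - 1 filtered - 1 duplicate
  expect_identical(rep_$n_neg_na, 1L)
  expect_identical(attr(generate_rn_negatives(out[out$label == 1L, ],
                                              rn_config(2, 9)), "rn_target"), 4)
  # negative subsets recoverable
  expect_setequal(unique(out$negative_origin), c("none", "NA", "RN"))

  # no RN config: just the filtered, deduplicated union
  out2 <- assemble_dataset(pos, na_negatives = na)
  expect_identical(nrow(out2), 3L)
  expect_identical(sum(out2$label == 0L), 1L)
})

test_that("the generic column filter drops below-threshold rows", {
  df <- data.frame(peptide = c("NLVPMVATV", "GILGFVFTL"),
                   cdr3b = c("CASSIRSSF", "CASSQETQF"),
                   label = 1, score = c(0, 2))
  tab <- sample_table(df)
  out <- assemble_dataset(tab, column_filter = list(column = "score", min = 1))
  expect_identical(out$peptide, "GILGFVFTL")
  expect_identical(attr(out, "build_report")$n_quality_filtered, 1L)
})
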