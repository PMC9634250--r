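Package: tcrbench
Title: Benchmark Construction and Leakage Diagnosis for TCR-Epitope Binding Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building T-cell receptor (TCR) - peptide/pMHC binding
    benchmarks and for diagnosing train/test leakage in them. Implements
    length filtration and per-setting deduplication of binding tuples,
    randomized-recombination (RN) negative generation, random and peptide-wise
    hard train/test splits with audits, per-sequence class histograms and a
    CDR3-memorization oracle, BLOSUM50 sequence encoding with a small
    feed-forward baseline classifier, an AUROC/AUPR evaluation harness with
    per-peptide breakdowns, and a seeded synthetic-data generator that
    reproduces the statistical structure (heavy-tailed peptide usage,
    class-disjoint CDR3 repertoires, recombined negatives) under which
    memorization shortcuts arise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    pROC,
    Biostrings
Config/testthat/edition: 3
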