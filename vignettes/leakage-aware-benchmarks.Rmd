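---
title: "Leakage-aware benchmarks for TCR–epitope binding prediction"
author: "tcrbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leakage-aware benchmarks for TCR-epitope binding prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrbench)
```

## The problem

Predicting whether a T-cell receptor (TCR) recognizes a peptide–MHC complex
is usually framed as binary classification on amino-acid sequences: given a
peptide and a CDR3β loop (optionally CDR3α and the MHC allele), predict a
binding label. Published models report excellent AUROC under random
train/test splits of the public databases, yet these numbers can be almost
entirely an artifact of how the benchmark was assembled and split.

Two properties of the data drive this:

1. **Class-disjoint CDR3 repertoires.** When negatives come from negative
   assays, the set of CDR3 sequences seen in positives and the set seen in
   negatives barely overlap. A classifier can then label a sample from its
   CDR3 alone — memorize the sequence, ignore the peptide. Under a random
   split most test CDR3s were seen in training, so this shortcut evaluates
   as near-perfect classification.
2. **Peptide imbalance.** A handful of well-studied epitopes account for
   most tuples, so a random split almost surely places every peptide on
   both sides of the split. Nothing in the evaluation ever asks the model
   about a peptide it has not seen.

`tcrbench` packages the machinery to build such benchmarks reproducibly,
to split them in a way that actually tests generalization to unseen
peptides (the *hard split*), and to quantify the memorization shortcut
directly.

## The dataset-building pipeline

`assemble_dataset()` applies, in order: concatenation of positive and
assay-negative (NA) tables, length filtration, per-setting deduplication,
recombined-negative (RN) generation, and a final deduplication.

* **Length filtration** keeps peptides shorter than 16 residues, CDR3α of
  7–21 and CDR3β of 9–23 residues (inclusive). These bounds trim the small
  tail of long sequences that would otherwise inflate every padded
  encoding.
* **Deduplication** operates on the tuple-identity *setting* — either
  `(peptide, cdr3b)` or `(peptide, cdr3b, cdr3a, mhc)` — plus the label.
  The same physical assay deposited in two databases collapses to one row.
  An identity observed with *both* labels is contradictory; the default
  policy drops it entirely (`keep_positive` and `keep_first` are
  available). The choice is conservative: a benchmark should not contain
  tuples whose label depends on which source you trust.
* **RN generation** pairs a peptide (or pMHC complex) from one donor
  positive with the CDR3/gene block of another. The default `joint`
  pairing keeps each donor's α/β chains together, the conservative reading
  of "recombine the sequences found in the positive tuples"; an
  `independent` mode samples chains separately. Candidates sharing
  `(peptide, cdr3b)` with any positive are discarded — this collision rule
  is deliberately applied on those two fields even in the four-field
  setting. Two negatives are drawn per positive by default. Rejection
  sampling is capped at 50× the target before a shortfall is declared, so
  degenerate inputs terminate.

RN negatives are *presumed* non-binding: a recombined pair is unlikely to
bind because specificity is peptide-particular, but the presumption is
exactly that, and the synthetic generator (below) lets us study what
happens when it fails.

## Random and hard splits

`random_split()` draws the test set uniformly without replacement (80/20
by default). `hard_split()` instead samples whole peptides from
\(P_{l,u}\), the set of peptides observed in at least \(l\) and at most
\(u\) tuples, and moves *all* their rows to the test side until a minimum
test fraction (15% by default) is reached. The budget is a minimum, so the
achieved fraction generally overshoots. \(l\) guarantees held-out peptides
have a broad CDR3 repertoire; \(u\) prevents one frequent peptide from
soaking up the whole budget. For full-scale data the reference bounds are
\(l = 500, u = 10000\) in the two-field setting and \(l = 100, u = 5000\)
in the four-field setting; scaled-down simulations here use \(l = 100, u =
5000\). Eligible peptides are materialized in lexicographic order before
the seeded shuffle, so a split is reproducible across platforms.

`audit_split()` proves the guarantee: it reports the number of peptides
shared between train and test (zero for every hard split, by
construction), the shared CDR3 counts (legitimately positive — TCRs may
recur), the achieved fraction, and per-test-peptide class counts. Note
what the hard split does *not* control: test TCRs can be seen at training
time. Grouping is by peptide only.

## Diagnostics

`class_histogram()` counts, per unique sequence of a field, its positive
and negative occurrences; `disjointness_fraction()` reduces that to the
fraction of sequences seen in both classes (0 = fully disjoint).

`memorization_oracle()` makes the shortcut hypothesis executable: it
scores a test row only from its CDR3's smoothed training-set positive
frequency,
\[
  s(c) = \frac{\mathrm{pos}(c) + \alpha\,\hat\pi}{\mathrm{tot}(c) + \alpha},
\]
with \(\hat\pi\) the training positive rate and \(\alpha = 1\) a
pseudo-count; unseen sequences score exactly \(\hat\pi\). The smoothing
makes the oracle well-defined everywhere and avoids score ties at 0/1, and
the pseudo-count pulls rarely-seen sequences toward the prior. The oracle
is deliberately peptide-blind (permuting test peptides leaves its scores
bit-identical) and serves as a *leakage ceiling* to report next to any
model: if your model's random-split AUROC is close to the oracle's, the
benchmark — not the model — is doing the work.

## Encoding and the baseline classifier

Sequences are BLOSUM50-encoded: position \(i\) of a padded sequence
becomes the 20-vector of substitution scores of residue \(i\) against the
standard residues in alphabetical order; padding rows are zero. Per-field
padded lengths (peptide 15, CDR3β 23, CDR3α 21, MHC pseudo-sequence 34)
mirror the length-filter bounds so no post-filter sequence can overflow.
The canonical matrix ships with the package as a plain-text file. MHC
alleles are represented by user-supplied NetMHCpan-style pseudo-sequences
(`attach_pseudo_sequence()`); class I and II are treated identically, and
no pseudo-sequence table is bundled because its convention belongs to the
user's pipeline.

The baseline scorer is a deliberately small feed-forward network: one ReLU
hidden layer (32 units by default) on the flattened concatenated
encodings, trained with minibatch Adam. It stands in for the large
published architectures, which are out of scope here; what matters for the
benchmark-diagnosis purpose is that it is big enough to memorize sequence
identities and small enough for minutes-scale CPU training. Training
follows the validation-selection protocol: an internal stratified 80/20
split of the training table, AUROC evaluated after every epoch, and the
weights of the best epoch returned (`patience` stops training after 25
epochs without improvement; determinism is guaranteed given the seed).
The classification threshold for thresholded metrics is fixed at 0.5.

## Metrics

`compute_metrics()` returns AUROC (Mann–Whitney form, ties counted ½),
AUPR (non-interpolated step integral), and F1/precision/recall/accuracy at
the threshold. With a single class present the rank metrics are `NA` with
a classed warning rather than a hard failure, because the thresholded
metrics are still well-defined. `peptide_specific_auroc()` ranks within
each test peptide's rows — peptides with one class present are reported
as missing and must be excluded from averages — and
`aggregate_over_splits()` reports means with *population* standard
deviations over repeated splits (k is recorded so the sample version can
be recovered).

## The synthetic generator

`generate_dataset()` produces seeded datasets with the statistical
structure that the leakage phenomena rest on, so every claim above is
testable without downloading anything. Peptide tuple counts follow a
clipped power law (exponent 1.5 by default — real epitope databases are
heavy-tailed, though no particular fit is claimed); sequences are uniform
random strings within the filter bounds, so builder filters drop nothing.

Two ground-truth binding rules are provided:

* **Idiosyncratic** — all peptides read one shared CDR3 contact position,
  but each peptide accepts its own random 4-residue subset there, derived
  by hashing the peptide. Labels are deterministic within a peptide and
  independent across peptides, so nothing transfers: against recombined
  negatives, any scorer ignorant of a peptide's accept set sits at AUROC
  0.5 in expectation on that peptide's rows.
* **Motif (compatibility)** — one global map assigns each residue to one
  of four classes; a CDR3 binds a peptide iff the classes at a fixed
  peptide anchor position and a fixed CDR3 core position agree (think
  complementary chemistry at a contact pair). The map and both positions
  are global, so a model that learns them on training peptides can apply
  them to unseen ones. `motif_strength` (default 0.9) is the fraction of
  positive rows that satisfy the rule; the rest are corruptions.

Negative modes mirror the two real-world negative sources: `NA_style`
draws negative CDR3s from a pool disjoint from the positive pool
(reproducing class-disjoint repertoires exactly), and `RN_style` runs the
*production* `generate_rn_negatives()` code path on the generated
positives and labels every recombination 0, so the generator doubles as an
integration test of the builder.

### What the scenarios show — and their design rationale

Three packaged scenarios carry the main results (sizes chosen to keep the
full suite in CPU-minutes):

1. **Memorization** (`NA_style`, 30 peptides × 50–150 positives, pool
   1200, ~7700 rows): under a random 80/20 split, over 90% of test CDR3s
   are seen in training and the memorization oracle scores ≥ 0.95 AUROC
   while never reading a peptide.
2. **Generalization failure** (`RN_style` + idiosyncratic, 20 peptides ×
   100–400 positives, pool 3000, ~12–14k rows): the baseline trained on
   five hard splits (minimum 15% test, \(l=100, u=5000\), ≤ 200 epochs)
   averages ≈ 0.47 test AUROC. The same data under a random split trains
   to ≈ 0.86, the qualitative signature of benchmark overstatement.
3. **Harness sensitivity** (`RN_style` + motif, 200–300 peptides × 35–100
   positives, pool 600): the same hard-split regime yields mean test AUROC
   ≥ 0.7, demonstrating that the harness rewards genuinely transferable
   structure and would expose a broken trainer.

Two design points deserve explanation, because they were forced by
analysis rather than convenience:

* *A CDR3-only "global motif" is undetectable under RN negatives.* RN
  recombination draws its CDR3s from the positive rows, so the negative
  CDR3 marginal equals the positive CDR3 marginal by construction; any
  rule that reads the CDR3 alone gives Bayes AUROC exactly 0.5 against RN
  negatives. A transferable rule must therefore couple the peptide and the
  CDR3 — hence the compatibility form of the motif rule.
* *Transfer requires a wide peptide panel.* With 20 peptides (~17 in
  training), a network can separate the training peptides by arbitrary
  sequence features — the anchor position is statistically unidentifiable,
  and whatever is learned cannot transfer. Instrumented runs showed high
  rule alignment on training peptides and chance performance on held-out
  ones. The sensitivity scenario therefore uses many small peptides
  (200–300), which is also the realistic regime for the question it asks:
  you cannot learn cross-peptide rules from a handful of epitopes.
  Relatedly, a small CDR3 pool (high reuse) spreads each CDR3's positive
  occurrences over many peptides, which neutralizes a subtle conditioning
  artifact: with nearly-unique CDR3s, the rows removed by holding out a
  test peptide are exactly the test positives' own positive occurrences,
  so per-sequence training frequencies acquire an *anti*-correlation with
  test labels (the memorization oracle scores ~0.25–0.40 on hard-split
  test sets). That artifact is itself a leakage phenomenon of recombined
  negatives under peptide holdout, and it is why idiosyncratic hard-split
  AUROCs fall slightly *below* 0.5.

### What the generator does not emulate

Sequences are uniform random strings: no V(D)J recombination statistics,
no positional amino-acid bias, no germline-encoded similarity between
CDR3s, no allele-frequency realism, and binding rules far simpler than
biophysics. Passing tests on this data shows that the *pipeline and
harness* behave as designed — that hard splits prevent peptide leakage,
that memorization is detected and rewarded exactly where it should be —
not that any model generalizes on real TCR data.

## Numerical choices and degenerate inputs

* AUROC ties count ½; AUPR is the non-interpolated step integral;
  population SD for split aggregation. Precision is defined as 0 when
  nothing is predicted positive.
* All randomized operations take explicit integer seeds and restore the
  caller's RNG state; identical seeds give bit-identical outputs.
* `hard_split()` raises a classed error when \(P_{l,u}\) is empty and
  flags underfill when it exhausts before the budget; RN generation flags
  shortfall instead of looping forever; empty tables are legal inputs to
  the filters and histogram.
* The residue alphabet is strictly the 20 standard letters: B, J, O, U,
  X, Z and `*` are invalid everywhere, the strictest defensible reading;
  readers drop offending rows and count them rather than failing.
* A configurable CDR3 trimming hook is *not* provided: sequence
  homogenization conventions vary between databases, and silently
  rewriting sequences seemed worse than asking users to pre-process.

## Known limitations

The baseline is a probe, not a competitive predictor; its absolute AUROCs
matter only relative to the oracle and to chance. Hard splits group by
peptide only — TCR-side leakage (shared CDR3s across sides) is reported by
the audit but deliberately not prevented. The pipeline consumes
pre-exported tables; parsing native database export formats is out of
scope.
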