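# Quick constructors for small fixtures used across tests.

# Strip bookkeeping attributes so tables compare on content alone.
plain <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "row.names", "class")]
  x
}

make_table <- function(peptide, cdr3b, label, ..., setting = "pep_cdr3b") {
  sample_table(data.frame(peptide = peptide, cdr3b = cdr3b, label = label,
                          ..., stringsAsFactors = FALSE),
               setting = setting)
}

# A random valid table: `npep` peptides with multiplicities, labels mixed.
random_table <- function(npep = 5, rows = 40, seed = 1) {
  set.seed(seed)
  peps <- replicate(npep, paste(sample(c("A", "G", "K", "L", "S", "V"), 9,
                                       replace = TRUE), collapse = ""))
  cdrs <- replicate(rows, paste(sample(c("C", "A", "S", "R", "Y", "F"), 12,
                                       replace = TRUE), collapse = ""))
  make_table(sample(peps, rows, replace = TRUE), cdrs,
             sample(0:1, rows, replace = TRUE))
}
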