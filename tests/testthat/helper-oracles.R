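# Independent oracles for primer matching, built from Biostrings' IUPAC code
# map (not from the package's own tables), plus small sequence generators.

iupac_sets <- local({
  m <- strsplit(Biostrings::IUPAC_CODE_MAP, "", fixed = TRUE)
  names(m) <- names(Biostrings::IUPAC_CODE_MAP)
  m
})

oracle_compatible <- function(a, b) {
  length(intersect(iupac_sets[[a]], iupac_sets[[b]])) > 0
}

oracle_revcomp <- function(s) {
  if (nchar(s) == 0) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Naive window scan: per-window mismatch count via the set-intersection rule.
# strand "minus": primer is laid 3'->5' along the plus strand.
oracle_window_counts <- function(primer_seq, template, strand) {
  p <- strsplit(if (strand == "plus") primer_seq else
    oracle_revcomp(primer_seq), "", fixed = TRUE)[[1]]
  tt <- strsplit(template, "", fixed = TRUE)[[1]]
  k <- length(p); n <- length(tt) - k + 1
  vapply(seq_len(n), function(s) {
    sum(!vapply(seq_len(k), function(j) oracle_compatible(p[j], tt[s + j - 1]),
                NA))
  }, 0L)
}

oracle_best_site <- function(primer_seq, template, strand) {
  mm <- oracle_window_counts(primer_seq, template, strand)
  i <- which.min(mm)
  list(start = i - 1L, total = mm[i])
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

random_iupac <- function(n, codes = c("A", "C", "G", "T", "R", "Y", "S", "W",
                                      "K", "M", "B", "D", "H", "V", "N")) {
  paste(sample(codes, n, TRUE, prob = c(rep(0.2, 4), rep(0.2 / 11, 11))),
        collapse = "")
}
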