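Package: cixscreen
Title: In Silico COI PCR Specificity Screening and Barcoding Phylogeny for
    Planthoppers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating species-specific PCR assays on the
    mitochondrial cytochrome oxidase I (COI) barcode, motivated by the
    detection of the sugar-beet planthopper Pentastiridius leporinus among
    morphologically similar cixiids. Implements IUPAC-aware degenerate
    primer matching with per-position mismatch profiles, a configurable
    3'-clamp extension rule, in silico PCR amplicon prediction and
    specificity matrices, discriminative primer-pair search on target
    alignments, pairwise-deletion evolutionary distances (p-distance,
    Jukes-Cantor, maximum composite likelihood), neighbor-joining trees
    with bootstrap supports and outgroup rooting, and a seeded simulator
    of COI-like sequence families and primer-site templates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
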