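Package: p53resig
Title: Sequence Signatures and Target-Gene Calling for Condition-Specific
    p53 Response Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Locates p53 response elements (REs) in ChIP-seq peak sequences
    with a half-site position weight matrix model that tolerates a short
    spacer between the two 10-bp half sites, builds per-position nucleotide
    count matrices and sequence-logo tables from RE sets, and compares two
    RE sets position by position with two-tailed Fisher's exact tests under
    Bonferroni correction to detect condition-specific sequence signatures
    (such as C at position 9 and G at position 12 of the 20-bp motif).
    Integrates differential p53 binding with differential expression to call
    regulated p53 target genes, annotating each gene's best RE with
    signature and conserved-position flags. A seeded simulator generates
    peak sequences with embedded REs, binding signals, and expression tables
    with planted effects so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
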