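Package: httev
Title: Evidence Chain for Horizontal Transfer of DNA Transposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assembles the standard chain of evidence used to distinguish
    horizontal transfer of DNA transposons from vertical inheritance:
    consensus (master) sequence reconstruction from genomic copies,
    copy-number calling from BLAST-style homology hit tables (including
    MITE-specific merge rules), target-site-duplication inference and
    empty-site verification, Kimura 2-parameter insertion dating via
    T = k/2r, Nei-Gojobori ds/dn and Wright's effective number of codons
    as purifying-selection controls, and a per-species-pair verdict that
    compares observed transposon divergence with the neutral expectation
    for the host split time. A synthetic-data generator simulates
    amplification bursts, TSD-bearing insertions and coding-sequence
    pairs with known ground truth so every stage is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
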