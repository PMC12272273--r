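Package: offscreen
Title: In Silico Off-Target Screening of dsRNA Biopesticide Constructs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens double-stranded RNA (dsRNA) biopesticide constructs for
    potential off-target silencing in non-target organisms. Emulates Dicer
    processing by exhaustive fragmentation of the construct into all unique
    21-mers, searches each small interfering RNA (siRNA) candidate against
    transcript databases with a deterministic mismatch-tolerant ungapped
    scan, applies a three-tier filter funnel (overall identity, near-perfect
    stretch, seed-region identity at guide positions 2-8), and reports
    per-transcript off-target sites and mismatch-class distributions. A
    synthetic transcriptome generator plants off-target sites with known
    identity, mismatch and seed structure so the whole analysis can be
    validated against ground truth without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
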