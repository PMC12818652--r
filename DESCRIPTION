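Package: inexr
Title: Alternative 5' Splice-Donor Usage Analysis via the In-Ex Ratio
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the relative usage of two alternative 5' splice donor
    sites feeding a shared acceptor, as in the KIT GN[N/S]K+/- isoform pair,
    from splice-junction evidence tables. Classifies junction reads as
    inclusion or exclusion, computes the in-ex ratio per sample, applies
    expression and read-depth sample filters, and compares per-tissue ratio
    distributions with exact 1-D Wasserstein distances, complete-linkage
    clustering, and exact Wilcoxon rank-sum tests with rank-based effect
    sizes. Also ranks genes by correlation with the in-ex ratio for
    pre-ranked gene-set enrichment, scores NOVA-family YCAY motif clusters
    in 45-nt sliding windows, detects GU-rich stretches, and simulates
    cohorts, expression matrices, junction files, and sequences with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    ape,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
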