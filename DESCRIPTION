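Package: hifmeta
Title: Consensus HIF Target-Gene Signatures and Metagene Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives consensus hypoxia-inducible factor (HIF) target-gene
    signatures from replicate ChIP-seq peak lists combined with
    differential-expression tables, scores HIF-pathway activation in bulk
    and single-cell expression matrices with a quantile-normalized
    metagene, and runs downstream association screens: per-gene
    correlation with the metagene, cross-dataset sharing counts,
    pre-ranked gene set enrichment analysis, covariate-adjusted
    regression, and group comparisons.  Includes seeded synthetic-data
    generators (cell-line panel, bulk tumor cohort, sparse single-cell
    counts) with planted ground truth so the full analysis chain is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
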