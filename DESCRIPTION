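Package: ladmeth
Title: LAD-Centric Differential Methylation and Multi-Omic Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrative toolkit for studying epigenetic deregulation of
    lamina-associated domains (LADs) in premature-aging fibroblasts.
    Implements probe-level differential methylation testing with
    empirical-Bayes variance moderation, bounded CpG probe clustering,
    resampling consensus clustering for sample subtyping, signed
    observed/expected fold-enrichment statistics for annotation tracks
    (LADs, solo-WCGW PMD/HMD strata, histone marks), poised-enhancer
    calling, ChIP/input log2 signal enrichment over LAD segments,
    epigenetic-age estimation with a culture-passage doubling factor,
    and multi-omic integration of differential methylation, chromatin
    accessibility and expression, including a distance-to-nearest-LAD
    test. A seeded synthetic-data generator emulates the statistical
    structure of the study design so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
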