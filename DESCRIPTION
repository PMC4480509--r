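Package: scvarcal
Title: Calibrated Analysis of Single-Cell Transcriptome Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for separating biological from technical variation in
    deep single-cell RNA-seq experiments that include dilution-control
    replicates (bulk RNA amplified from single-cell input amounts).
    Implements median-of-ratios depth normalization, selection of a
    reliable-quantification expression threshold from four control-based
    criteria, an expression-level-matched F-statistic for within-cell-type
    variability, outlier-sum and Shapiro-Wilk classification of extreme
    and consistent expression patterns, cross-species partial correlation
    of variability, common-gene overlap testing, 3' UTR termination-site
    detection from strand-resolved read-start coverage, and a synthetic
    data generator emulating the full study design for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    multcomp,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    DESeq2,
    Matrix
Config/testthat/edition: 3
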