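Package: cfmodal
Title: Multimodal Cell-Free DNA Methylome, Fragmentation and Copy-Number Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-genome cell-free DNA (cfDNA)
    methylation sequencing with simultaneous genetic readouts. Builds
    window-level methylation matrices from per-CpG call tables with
    exclusion masks and spike-in conversion QC; performs principal
    component analysis with feature-overlap enrichment; trains two-class
    cancer/control classifiers with differentially methylated region (DMR)
    selection nested inside leave-one-out cross-validation; estimates
    tissue of origin by nonnegative least squares against an
    enhancer-aggregated tissue reference atlas; profiles fragment lengths
    in 10-bp bins; calls copy-number aberrations from binned read counts;
    and integrates three-class predictions from the methylation, tissue
    and fragmentation modalities by probability averaging. Includes a
    synthetic-data generator that emulates the statistical structure of a
    plasma cfDNA cohort so the full pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    glmnet,
    e1071,
    pracma
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite
Config/testthat/edition: 3
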