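Package: fraghound
Title: Cell-Free DNA Fragmentomics and Copy-Number Consensus Analysis for
    Canine Liquid Biopsies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for shallow whole-genome sequencing of
    cell-free DNA (cfDNA) in canine oncology, centred on hemangiosarcoma
    detection. Builds per-sample fragment-length histograms from paired-end
    alignments with samtools-style flag, mapping-quality and size filters;
    normalizes them into fragment-size distributions and cohort summaries;
    detects the principal mono-nucleosome peak and the ~10-bp sub-peak
    oscillation structure with its peak/valley "diff" statistics; performs
    repeated SVM-RFE feature-region discovery and a seven-algorithm
    classification bench with repeated hold-out and stratified k-fold
    cross-validation; and calls recurrent copy-number alterations by
    intersecting two binned-coverage callers and applying a cross-sample
    recurrence filter. A synthetic cohort generator reproduces the
    distributional structure of real cfDNA (nucleosome periodicity, tumor
    peak shift, spiked gains and losses) so the entire chain runs without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    e1071,
    randomForest,
    ranger,
    xgboost,
    rpart,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
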