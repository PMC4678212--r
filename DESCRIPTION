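Package: azflux
Title: Abscission-Zone Transcriptome Flux Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a comparative abscission-zone
    transcriptome workflow: RPKM normalization of raw read counts,
    platform-specific expression gates with floor substitution, log2
    AZ/NAZ specificity and time-course ratio statistics, the greater than
    8-fold plus p < 0.015 filter cascade, keyword-driven functional
    category assignment with percent-of-transcriptome profiles, and
    heat-map, time-course and capped volcano output tables. Includes a
    negative-binomial simulator for two-tissue ethylene time courses and
    two-genotype contrasts with planted effect classes, so every stage is
    testable against ground truth without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'AZExperiment-methods.R'
    'simulate.R'
    'normalize.R'
    'differential.R'
    'categories.R'
    'outputs.R'
    'io.R'
    'pipeline.R'
    'azflux-package.R'
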