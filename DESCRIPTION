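Package: cortexMS
Title: Moderated Differential Expression and TNF Pathway Balance Analysis
    for Cortical Microarray Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end expression-analysis pipeline for case-control
    microarray studies of the multiple sclerosis motor cortex: random-variance
    moderated t-tests for class comparison, balanced-permutation false
    discovery rate calibration with a stringency scan over p-value and
    fold-change thresholds, LS/KS/maxmean gene-set testing with a 2-of-3
    consensus rule, TNF pro-death versus pro-survival pathway balance scoring,
    average-linkage hierarchical clustering with the uncentered Pearson
    metric, and delta-Ct qPCR quantification with Mann-Whitney comparisons.
    A synthetic-data generator emulating the 5-group, 50-array lesion and
    normal-appearing grey matter design makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Microarray, DifferentialExpression, GeneSetEnrichment, qPCR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
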