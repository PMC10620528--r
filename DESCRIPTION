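Package: scfcoupling
Title: Structural-Functional Connectome Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the coupling between structural and functional brain
    connectomes at the node level.  Builds functional connectivity matrices
    from region-level BOLD time series (Pearson correlation, Fisher-Z
    transform, proportional sparsity thresholding), computes per-node
    structural-functional coupling as the Spearman rank correlation between
    matched rows of the structural and functional matrices, partitions nodes
    into coupling-homogeneous clusters by k-means with elbow-based model
    selection, derives cluster-averaged (ASFC) and within-cluster edge-profile
    (CSFC) coupling indices, and runs covariate-adjusted group contrasts and
    partial correlations with clinical variables.  Includes a synthetic
    connectome cohort generator with planted coupling strata, planted group
    decoupling and planted clinical correlations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
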