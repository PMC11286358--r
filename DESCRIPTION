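Package: vnndrug
Title: Hierarchy-Guided Visible Neural Networks for Drug-Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and interprets visible neural networks (VNNs)
    whose layers mirror a nested hierarchy of protein assemblies. Binary
    per-gene alteration profiles (mutation, copy-number amplification,
    copy-number deletion) are embedded gene by gene and propagated through
    assembly-shaped neuron blocks to predict a continuous drug-response AUC.
    Includes grouped nested cross-validation, ridge-probe assembly importance
    with structure-preserving permutation nulls and Benjamini-Hochberg
    control, core-assembly selection, response classification with diagnostic
    odds ratios, L1-logistic alteration ranking, CRISPR-screen scoring and
    gene-set enrichment, survival comparisons, and a synthetic-data generator
    with planted causal assemblies for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
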