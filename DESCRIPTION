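Package: gpensemble
Title: Ensemble Genomic Prediction with Diversity Decomposition for NAM Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for ensemble genomic prediction in
    nested association mapping (NAM) recombinant inbred line populations. Provides
    a gamete-level RIL simulator with Haldane recombination, the standard
    preprocessing chain for NAM marker panels (flanking-marker imputation, sample
    filters, windowed LD pruning, multi-environment concatenation, BLUP/BLUE
    derivation), additive and additive-by-additive genomic relationship matrices
    with an extended GBLUP REML fit for variance partitioning, six genomic
    prediction models (rrBLUP, BayesB, RKHS, random forest, support vector
    regression, multilayer perceptron) behind a uniform fit/predict contract,
    equal-weight ensemble averaging with the Diversity Prediction Theorem
    decomposition of ensemble error, and marker-effect inference (allele
    substitution effects, impurity importance, Shapley scores and pairwise
    Shapley interactions) mapped to quantile-binned genome tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
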