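Package: tfmicro
Title: Transfer-Function Models and Mirror-Statistic Inference for
    Microbiome Intervention Time Series
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models multi-subject microbial count time series under
    environmental interventions using transfer-function models: per-taxon
    componentwise linear boosting on lagged community, intervention and
    host-covariate features, with randomized interaction screening.
    Supports h-step forecasting with observed-value substitution,
    counterfactual trajectory simulation under hypothetical intervention
    paths, and taxon selection via partial-dependence mirror statistics
    with false discovery rate control by data splitting and multi-split
    aggregation. Ships a negative-binomial autoregressive benchmark
    simulator with phylogenetic noise and ground-truth labels, a
    Lotka-Volterra toy system, normalization variants (median-of-ratios
    size factors, asinh, TSS, CLR), and forecasting/inference metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
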