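Package: bslmm
Title: Bayesian Sparse Linear Mixed Models for Polygenic Modeling
Version: 0.1.0
Authors@R:
    person("BSLMM", "Maintainers", email = "maintainers@bslmm.dev",
           role = c("aut", "cre"))
Description: Fits Bayesian sparse linear mixed models (BSLMM) to quantitative
    and 1/0-coded binary traits for polygenic modeling in genome-wide
    association data. Estimates the proportion of phenotypic variance
    explained by genotypes (PVE, "chip heritability") and the share of that
    genetic variance attributable to large sparse effects (PGE), computes
    per-SNP posterior inclusion probabilities, and predicts phenotypes for
    new individuals. The model bridges the linear mixed model (ridge
    regression / BLUP) and Bayesian variable selection regression, both of
    which are available as exact special cases. Posterior inference uses
    Metropolis-Hastings sampling with the sparse effects, intercept and
    residual precision integrated out analytically; a single kinship
    eigendecomposition makes each likelihood evaluation linear in the number
    of individuals. Includes a GWAS-like genotype and phenotype simulator
    with exact control of the realized PVE, REML estimation for the pure
    mixed model, prediction metrics (RMSE, correlation, relative predictive
    gain, AUC, Brier score), a liability-scale correction for case-control
    PVE, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
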