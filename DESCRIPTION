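Package: hbmgwas
Title: Spike-and-Slab Hierarchical Bayesian Models for Genome-Wide
    Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits a hierarchical Bayesian model for genome-wide association
    studies in which SNP effects follow a mixture of a point mass at zero
    and a normal distribution, estimated by a component-wise Gibbs sampler
    that scales to large SNP panels. Includes a restricted maximum
    likelihood (REML) mixed-linear-model baseline on the genomic
    relationship matrix, estimators of the proportion of phenotypic
    variance explained (PVE), genotype quality control and relatedness
    pruning, a single-SNP marginal scan with a p-value-threshold
    multiscale PVE analysis, and a calibrated sparse polygenic phenotype
    simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
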