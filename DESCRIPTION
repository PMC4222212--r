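Package: introquant
Title: Quantifying Unidirectional Genetic Introgression with In Silico
    Center Points
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A standardized pipeline for quantifying unidirectional
    (domesticated-to-wild) genetic introgression from diagnostic SNP
    panels. Synthesizes Hardy-Weinberg "center point" reference
    populations in silico by frequency-conditional random mating,
    assigns individuals one by one to the two center points with a
    two-cluster Bayesian admixture model (Gibbs sampler, with a fast
    fixed-frequency maximum-likelihood estimator), builds reference
    P(wild) distributions, tests contemporary samples for introgression
    with or without population-specific historical references, and
    estimates the proportion of wild genome left with bootstrap
    confidence intervals. Includes gamete-level hybrid-cross simulators
    and a Balding-Nichols synthetic genotype generator so the whole
    workflow can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
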