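Package: sgepig
Title: Social Genetic Effects on Growth and Sow Longevity in Pigs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian multi-trait linear-threshold animal models with social
    (indirect) genetic effects for pig breeding data. Implements pedigree
    relationship matrices and their sparse inverses, dilution-adjusted social
    incidence structures, a Gibbs sampler with liability augmentation for
    binary stayability, highest-posterior-density chain summaries, derived
    genetic parameters (total breeding values, total heritable variance,
    correlations among direct, social and total breeding values), and a
    synthetic herd generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
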