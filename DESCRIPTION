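Package: islandpop
Title: Two-Marker Population Genetics for Island Endemics: Diversity,
    Structure and Coalescent ABC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for joint mitochondrial-microsatellite population
    genetic inference in small, fragmented populations. Implements
    sequence diversity and neutrality statistics (Fu and Li's D* and F*,
    R2, mismatch distributions with a sudden-expansion fit), Tamura
    three-parameter distances with gamma rate heterogeneity and
    distance-based molecular dating, median-joining haplotype networks,
    Weir-Cockerham F-statistics with permutation tests, rarefied allelic
    richness, Queller-Goodnight relatedness, likelihood-based individual
    inbreeding coefficients, a Bayesian admixture (STRUCTURE-type) Gibbs
    sampler with Evanno delta-K model selection and replicate alignment,
    discriminant analysis of principal components, and a coalescent
    simulation engine for approximate Bayesian computation: demographic
    scenario choice by linear discriminant projection with multinomial
    logistic regression, local-linear posterior parameter estimation with
    logit transformation, pseudo-observed-dataset validation and posterior
    predictive model checking. A synthetic-study generator produces
    complete two-marker datasets with known ground truth for method
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    MASS,
    nnet,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
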