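Package: milkCH4
Title: Indirect Methane Phenotypes from Milk Records and Genetic
    Parameters by Pedigree REML
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts per-lactation enteric methane of dairy cows from
    routinely recorded milk yield and composition (energy-corrected milk,
    protein concentration and three published prediction equations), and
    estimates genetic parameters of the predicted phenotypes with
    pedigree-based repeatability animal models.  Provides pedigree
    parsing and pruning, the numerator relationship matrix, inbreeding by
    the Meuwissen-Luo algorithm and the sparse inverse relationship
    matrix by Henderson's rules; REML variance-component estimation
    (EM steps with average-information acceleration on Henderson's
    mixed-model equations) for univariate and bivariate models;
    heritability, repeatability and genetic/phenotypic correlations with
    delta-method standard errors; a synthetic-herd generator for
    validation by parameter recovery; and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
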