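Package: ratelink
Title: Linking Rates of Molecular and Phenotypic Evolution Across Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genotype-phenotype associations across species without
    assuming directional change, by coupling branch-wise rates of phenotypic
    evolution with branch-wise rates of molecular evolution. Implements a
    Bayesian variable-rates phylogenetic regression (branch-specific Brownian
    rate scalars estimated by reversible-jump MCMC, with stepping-stone
    marginal likelihoods and Bayes factors), MG94xREV codon substitution
    models with per-branch synonymous and non-synonymous rates and a
    likelihood-ratio test for branch-to-branch rate variation, root-to-tip
    evolutionary path sums, Bayesian phylogenetic generalized least squares
    with Pagel's lambda, and a driver/moderator classification of genes from
    the joint pattern of phenotype-level and rate-level associations. A
    rate-coupled simulator of trees, trait tables and codon alignments
    provides calibrated synthetic benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
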