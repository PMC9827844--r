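Package: evopath
Title: Evolutionary Pathway Inference for Correlated Binary Trait Evolution on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-layer Bayesian comparative analysis for pairs of binary traits on a
    time-calibrated phylogeny. A phylogenetic probit (threshold) model screens a binary
    response trait against multiple binary predictors with collinearity (VIF) checks,
    posterior effect sizes, Px significance and liability-scale heritability. Trait
    pairs that pass the screen are analysed under a 4-state continuous-time Markov
    model of correlated evolution, estimated by reversible-jump MCMC with a zero-rate
    bin and an exponential prior whose mean carries a uniform hyperprior; marginal
    likelihoods via stepping-stone sampling compare the dependent against the
    independent model, and posterior transition-rate inequalities are mapped to
    explicit evolutionary-pathway verdicts (ecology-first, care-first,
    alternative-solutions, unrelated). Includes a synthetic-data generator (Yule trees,
    Gillespie trait histories under named regime presets) so the whole pipeline can be
    exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    coda,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    expm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
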