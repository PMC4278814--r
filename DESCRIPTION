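Package: windborne
Title: Reconstructing Windborne Insect Invasions from Wind, Survey and
    Microsatellite Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to reconstruct the secondary expansion of a windborne
    invasive insect across a fragmented host landscape.  Builds grid-based
    wind-exposure covariates from particle-trajectory data under competing
    dispersal scenarios, fits an interval-censored Poisson establishment
    model with time-dependent covariates by maximum likelihood, computes
    classical microsatellite population-genetic statistics (diversity,
    rarefied allelic richness, Weir-Cockerham F-statistics, R-statistics,
    AMOVA, isolation-by-distance permutation tests, null-allele EM), and
    performs coalescent-based approximate Bayesian computation model choice
    among dated deme-founding scenarios with a generalized stepwise
    microsatellite mutation model.  A synthetic-data generator emulates all
    input kinds so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
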