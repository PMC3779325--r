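Package: bathydiv
Title: Diversification, Mass-Extinction and Comparative Analyses for
    Deep-Sea Mussel Radiations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood tools for studying the tempo and drivers of an
    adaptive radiation on a time-calibrated phylogeny, motivated by
    chemosymbiotic deep-sea mussels (Bathymodiolinae and relatives).
    Implements birth-death and multi-rate Yule diversification models on
    branching times with AIC model selection and a simulation-based
    rate-shift test; an episodic birth-death likelihood with instantaneous
    mass-extinction events and the matching simulation test; binary-state
    speciation and extinction (BiSSE) likelihoods with Yule-constrained
    character-dependent model comparisons; Mk and Brownian ancestral-state
    reconstruction; Pagel's correlation test, phylogenetic ANOVA,
    phylogenetic generalized least squares and depth-habitat comparisons;
    nonparametric rate smoothing for divergence dating with
    offset-exponential fossil calibration utilities; and seeded simulators
    for trees (constant, episodic, mass-extinction and state-dependent
    regimes) and discrete/continuous traits that emulate the structure of
    the empirical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    Matrix,
    nlme,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
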