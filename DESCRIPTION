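Package: patchforage
Title: Optimal-Agent Modelling and Behavioral Analysis for a Timed
    Patch-Foraging Task
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Formalizes a timed patch-foraging task in which a forager
    harvests depleting resource patches (four areas of five coin boxes
    each) under a fixed time budget, and solves for the reward-maximizing
    policy by backward induction over a stochastic decision tree with
    exact belief updating over the hidden rich/poor layout.  Provides
    Monte-Carlo policy rollouts, a synthetic cohort generator with
    softmax decision noise and timing variability, and the behavioral
    analysis stage: per-trial dependent variables, timing-parameter
    estimation, area-switch probabilities, trend fits, and agent-versus-
    optimal contrasts.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
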