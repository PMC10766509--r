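Package: guidedtps
Title: Machine-Guided Transition Path Sampling with Committor Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An autonomous transition path sampling (TPS) loop that learns the
    committor function of a rare event while sampling it. Two-way shooting
    moves generate Bernoulli shooting outcomes from which a parametric
    log-predictor of the committor is estimated by maximum likelihood; the
    learned model is validated on the fly by comparing expected and generated
    transition-path counts, biases shooting-point selection towards the
    learned transition-state ensemble via a Lorentzian selection density, and
    is finally distilled into compact symbolic expressions by an (N+1)
    evolution strategy with a complexity penalty. Ships with toy Langevin
    systems (1D quartic double well, 2D two-channel well) with analytic
    committor oracles, Behler-style G2/G5 symmetry-function featurization,
    permutation-importance attribution, and transition-path ensemble analysis
    (dynamic time warping, hierarchical clustering, per-path density maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
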