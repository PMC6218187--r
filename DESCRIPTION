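Package: mivac
Title: Mutual Inhibition with Value-Based Attentional Capture for
    Multi-Alternative Decision Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, simulation-based maximum-likelihood fitting, and model
    comparison for the MIVAC accumulator model of multi-alternative value-based
    choice: a race of leaky, mutually inhibiting accumulators under a linearly
    collapsing bound, extended with value-dependent fixation probabilities
    (value-based attentional capture), an additive input boost for the fixated
    option, and probabilistic identification of an unavailable distractor.
    Includes the two-attribute gamble task designs (rejection-sampled choice
    sets with a bounded shared-variance criterion and the combinatorial
    Dominance-by-Similarity distractor set), static baseline choice models
    (single-attribute, expected-value, expected-utility, prospect-theory, and
    multinomial-logit variants), a multi-attribute comparison extension for
    context effects, synthetic-cohort generation with fixation streams, and the
    within-participant statistical battery, including a demonstration that an
    uncentered product term in a logistic regression induces a spurious
    distractor-value effect through nonessential multicollinearity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
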