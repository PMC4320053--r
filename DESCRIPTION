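Package: rhibayes
Title: Bayesian Causal Inference Modeling and Analysis of the Rubber Hand
    Illusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the Bayesian causal-inference account of the rubber
    hand illusion: closed-form marginal likelihoods and the posterior
    probability of a common cause for visual-proprioceptive spatial cues and
    visual-tactile temporal cues, with model-averaged stimulus estimates
    under squared-error loss. Provides a seeded Monte Carlo simulator for
    synchronous, asynchronous and no-stroking conditions, a rubber-hand
    distance sweep with prior-width calibration, an analysis pipeline for
    proprioceptive-drift, ownership-rating and skin-conductance experiments,
    and generators for synthetic experimental cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    nortest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
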