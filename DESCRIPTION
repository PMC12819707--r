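Package: hapticue
Title: Simulation and Bayesian Model Comparison for Haptic Cue Combination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how observers combine cutaneous and
    proprioceptive (finger configuration) cues when judging the size of a
    disk held between thumb and index finger.  Implements three perceptual
    strategies (winner-take-all, unweighted averaging, and reliability-
    weighted optimal averaging), a two-interval forced-choice experiment
    simulator including oval cue-conflict stimuli, Bayesian grid estimation
    of psychometric parameters, entropy-based adaptive stimulus selection,
    and classification of observers by sampled-triplet marginal likelihoods.
    Includes population-level simulation pipelines that quantify how
    accurately the classification procedure recovers an observer's true
    strategy in non-conflict and cue-conflict designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
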