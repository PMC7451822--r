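Package: avoidrl
Title: Actor-Critic Modeling of Active Escape-Avoidance Learning in Rats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modeling operant escape-avoidance learning with a
    two-action actor-critic temporal-difference model over five binary
    stimuli (danger signal, safety signal, shock, chamber, homecage).
    Includes a 12-second-resolution simulator of the lever-press avoidance
    task, trial-by-trial negative log-likelihood computation, exhaustive
    grid-search maximum-likelihood parameter estimation, behavioral-recovery
    simulation with avoidance/escape/anticipatory/inter-trial response
    scoring, synthetic-cohort generation for parameter-recovery studies,
    and readers/writers for the associated CSV file formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
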