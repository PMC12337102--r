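Package: ecodec
Title: Streaming Speech-Event Detection, Verification and Decoding from
    Electrocorticographic Neural Features
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for decoding attempted speech from multichannel
    sensorimotor electrocorticography (ECoG). Implements extraction of
    high-gamma amplitude and low-frequency neural feature streams with
    streaming normalization and artifact screening; a causal recurrent
    speech-detection model with probability/time-threshold event
    extraction; an ensemble verification gate that separates attempted
    speech from reading and listening; closed-vocabulary word
    classification with time-window and electrode-set ablations; event
    matching and statistical evaluation utilities; offline electrode
    responsiveness and contribution mapping with multitaper band-power
    contrasts; and a seeded simulator of sensorimotor ECoG feature
    streams that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
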