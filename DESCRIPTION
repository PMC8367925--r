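Package: cohorttrace
Title: Cohort Prediction Error and Interactive-Activation Simulations of
    Spoken Word Recognition
Version: 0.1.0
Authors@R:
    person("Maglab", "Replication", email = "dev@example.org", role = c("aut", "cre"))
Description: Tools to ask whether signal reduction for expected speech input
    is diagnostic of predictive coding.  Implements a frequency-weighted
    cohort model of by-position phoneme prediction and summed-absolute
    prediction error, an instrumented interactive-activation (TRACE-family)
    simulator of spoken word recognition with lexical feedback and lateral
    inhibition, a novel-word-learning experiment harness with deviation-point
    alignment and counterbalancing, and a synthetic lexicon and stimulus
    generator so the full pipeline runs without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
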