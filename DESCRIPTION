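Package: cbdcoin
Title: Contextuality-by-Default Analysis of Forced-Choice Judgments as
    Generalized Coins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether two-alternative forced-choice
    judgments form a quantum-like contextual system when arranged as a
    cyclic (4-cycle) set of measurement contexts.  Implements the
    generalized-coin data model, the probability-scale disturbance
    statistic, the s_odd correlation statistic under both the convention
    used in the behavioural literature and the canonical
    Contextuality-by-Default definition, Boole's conditions of possible
    experience, percentile-bootstrap confidence intervals for the
    contextuality statistic, a generalized-coin toss simulator, and a
    synthetic judgment-data generator emulating a between-subjects
    real-versus-AI-face discrimination study.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
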