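Package: klepsydra
Title: Dual Klepsydra Model Analysis of Duration Reproduction Data
Version: 0.1.0
Authors@R:
    person("Klepsydra", "Maintainers", email = "klepsydra@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing duration reproduction experiments with the
    dual klepsydra model (DKM), in which attended durations are represented by
    the states of lossy integrators ("klepsydrae") that fill at a constant
    inflow and leak in proportion to their momentary state. Provides the
    closed-form klepsydraic reproduction function and a brute-force dynamical
    oracle for validating it, per-subject estimation of the outflow rate kappa
    and per-condition inflow ratios eta, model-free aggregate ratio indices,
    a statistical battery (one-sample and paired t-tests, repeated-measures
    ANOVA with Greenhouse-Geisser correction, Pearson correlation, and
    fixed-bandwidth Gaussian kernel density estimation), a seeded synthetic
    cohort generator emulating a 31-subject, 45-trial affective-sounds study
    design, and a command-line pipeline from trial-level CSV files to a
    machine-readable analysis report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
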