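Package: circapanel
Title: Circadian Rhythmicity Testing and Damped Cosinor Fitting for
    qPCR Time-Course Panels
Version: 0.1.0
Authors@R:
    person("circapanel", "developers", email = "circapanel@example.org",
           role = c("aut", "cre"))
Description: Analysis of replicated circadian gene-expression time courses
    from qPCR experiments on synchronized cell cultures. Converts raw
    cycle-threshold (Ct) tables to relative expression via the 2^-ddCt
    method, screens series for rhythmicity with a battery of complementary
    tests (Lomb-Scargle permutation test, a JTK-Cycle-style Kendall-tau
    template test, a RAIN-style umbrella test, and a bounded-period
    damped-cosine fit test), compares rhythms between conditions with a
    robust harmonic-regression differential test, and estimates circadian
    parameters (amplitude, damping/growth rate, phase, period, linear
    baseline) by weighted nonlinear fitting of a damped cosine with a
    linear baseline. Includes a synthetic-data generator emulating the
    serum-shock qPCR study design (0-48 h sampling every 4 h, 5-6
    replicates per time point) so every stage is testable end to end,
    plus a command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
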