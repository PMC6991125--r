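Package: churchill
Title: Growth-and-Decline Trajectory Analysis for Batch Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the Churchill-Usagi blended-asymptote growth-and-decline
    equation to per-replicate cell-count time series from batch cultures
    (e.g. flow-cytometric counts of marine diatoms), derives the growth
    exponent, maximum abundance, and decline exponent for each replicate,
    and runs factorial cell-means inference with multiplicity-adjusted
    marginal-mean contrasts and a percent-impact effect metric.  Includes
    a seeded synthetic-experiment generator emulating a host x inoculum x
    vitamin factorial design, CSV input/output for tidy count tables, and
    a command-line pipeline (simulate, fit, compare, report).
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    graphics,
    yaml
Suggests: testthat (>= 3.0.0), emmeans, withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
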