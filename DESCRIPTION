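Package: streamresp
Title: Stream-Side Intermittent-Flow Respirometry and Thermal Risk Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing stream-side intermittent-flow respirometry
    trials on wild fish: segmentation of raw dissolved-oxygen traces into
    measurement and flush phases, background-corrected oxygen-consumption
    (MO2) estimation, derivation of standard and maximum metabolic rate,
    absolute and factorial aerobic scope, routine metabolic rate by
    temperature, Q10 temperature coefficients, and post-exercise recovery
    kinetics (time to 50% MMR, time to end of EPOC via a smoothing spline).
    A thermal-risk layer combines critical thermal maximum trials with
    stream temperature projections to compute thermal safety margins,
    T-pejus from a factorial-aerobic-scope threshold, and functional
    warming tolerance. Includes rank-based group comparison statistics
    (Kruskal-Wallis, Dunn's post hoc, one-way ANOVA), a log-linear model of
    routine metabolic rate on temperature, a synthetic trial generator with
    known ground truth for validation, and an end-to-end pipeline driver.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
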