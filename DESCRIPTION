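Package: oxtouch
Title: Simulation and Analysis Pipeline for Oxytocin Modulation of Affective
    Touch fNIRS Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an end-to-end analysis pipeline for randomized
    oxytocin / social-touch studies recorded with functional near-infrared
    spectroscopy (fNIRS): a synthetic cohort generator emulating a
    three-arm (intranasal oxytocin, oral oxytocin, placebo) block-design
    experiment; fNIRS preprocessing (optical density, modified
    Beer-Lambert conversion, polynomial detrending, temporal derivative
    distribution repair, zero-phase Butterworth bandpass); first-level
    GLM with canonical double-gamma regressors, stimulation-minus-rest
    contrasts and region-of-interest aggregation; leave-one-out
    correlation-based group classification with permutation significance;
    autonomic indices (event-locked skin conductance amplitude, heart
    rate, high-frequency heart-rate-variability power, detrended
    fluctuation analysis alpha-1); and an inferential layer with mixed
    repeated-measures ANOVAs, bootstrap mediation through plasma oxytocin
    changes, and a noncentral-F a-priori sample-size solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
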