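Package: phasestates
Title: Phase-Coherence Brain States and State-Conditioned Auditory Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for dynamic functional-connectivity brain-state analysis of
    ROI-level fMRI time series and for relating ongoing brain states to
    near-threshold auditory detection behavior. Converts ROI signals to
    instantaneous phases (analytic signal), represents each fMRI volume as a
    vector of pairwise phase-coherence values, learns a dictionary of
    recurrent connectivity patterns by k-means clustering under the Manhattan
    distance with silhouette-based model-order selection, labels task volumes
    with the nearest rest-trained centroid, and runs a circular-shift
    surrogate control. Includes state-conditioned behavioral statistics
    (arcsine-rate and inverse-RT linear mixed models with Wald tests and
    FDR-corrected contrasts, Wilcoxon signed-rank comparisons, post-stimulus
    and time-resolved state-occupancy analyses, Spearman rating correlations)
    and a fully synthetic multi-subject generator (Markov-switching coherence
    templates, randomized trial schedules, a logistic observer with
    state-dependent detection and hysteresis, and a one-up-one-down staircase)
    so the entire pipeline can be exercised and validated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    graphics,
    cluster,
    lme4,
    car,
    emmeans,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
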