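Package: optoephys
Title: Layer-Resolved Optogenetic Electrophysiology and Behavior Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for layer-resolved optogenetic
    electrophysiology and sensory/affective behavior. Reads Phy/Kilosort-style
    sorted spike directories and trial event tables, performs unit quality
    control, optotagging by first-spike latency and jitter, depth-to-layer
    registration, and computes per-unit, per-condition response metrics
    (mean rate, modulation index, response probability, burst probability,
    ISI distributions). Modulation significance combines a paired Wilcoxon
    signed-rank count test with a time-locked deviation (ZETA-style) test
    with a resampling null. Population proportions are compared with a
    chi-square homogeneity test plus the Marascuillo procedure, McNemar's
    exact test, Friedman and rank-sum tests, all with exact small-sample
    branches. Behavioral readouts include von Frey psychometric curves under
    the ascending stop rule, 60 percent withdrawal thresholds, sensitization
    AUC, paw-lift intensity thresholds, and place-preference indices.
    Fiber-optic irradiance at the tip and at cortical depth is estimated from
    fiber geometry and a tissue attenuation model. A synthetic-data module
    generates spike trains and behavior sessions with known ground truth so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
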