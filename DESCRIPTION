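Package: wmdrift
Title: Cross-Session Population Decoding and Representational Drift Analysis
    for Working-Memory Tasks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis machinery for multi-day calcium-imaging recordings from
    mice performing an olfactory delayed-association working-memory task:
    trial-aligned activity binning and epoch statistics, behavioural
    performance and d-prime, circular-shuffle activity-field tests, rank-sum
    odour/choice selectivity with pure/mixed classification, linear population
    decoding with repeated stratified splits and label-shuffle chance,
    depth-stratified and cross-day decoder-generalization analyses on
    centroid-matched neurons, day-shuffle stability tests, and
    crystallization-day (change-point) estimation. Includes a synthetic-cohort
    generator with planted tuning, drift/stabilization schedules, depth
    gradients and behavioural error models so that every stage is verifiable
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'wmdrift-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'task_model.R'
    'synthetic.R'
    'behaviour.R'
    'selectivity.R'
    'decoding.R'
    'registration.R'
    'stability.R'
    'pipeline.R'
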