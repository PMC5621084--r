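Package: PostureSense
Title: Posture Classification from Instrumented-Insole and Helmet-IMU Recordings
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying adequate and inadequate work postures from
    two wearable sensors: a four-sensor instrumented insole and a helmet-mounted
    accelerometer. Computes center-of-pressure (COP) trajectories from insole
    pressures, extracts a 60-feature bank of posturographic and head-acceleration
    statistics plus binary occupancy-grid features from the rasterized COP
    trajectory, reduces dimensionality with a hybrid filter (Fisher score,
    two-sample t, Pearson, ANOVA, ReliefF) plus sequential-forward-selection
    wrapper, and classifies six work situations with a single-hidden-layer
    tanh/softmax neural network under repeated stratified cross-validation.
    Includes a seeded synthetic-trial generator so the full pipeline can be
    exercised and benchmarked without access to participant recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    pracma,
    S4Vectors,
    SummarizedExperiment
Suggests:
    nnet,
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cop.R'
    'features-direct.R'
    'classifier.R'
    'features-graphic.R'
    'selection.R'
    'recordings-io.R'
    'synthetic.R'
    'pipeline.R'
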