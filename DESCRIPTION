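Package: emgrasp
Title: Object-Grasp Classification from EMG and IMU Signals under Limb-Position Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for studying the limb-position effect in
    myoelectric control. Simulates labeled multi-channel surface-EMG and IMU
    recordings of object grasps performed at nine placement positions, filters
    and segments them into 150 ms analysis windows, extracts the classical
    time-domain feature set (MAV, ZC, WL, SSC, sixth-order AR coefficients,
    IMU RMS; 66 dimensions), reduces dimensionality with PCA, LDA, a spectral
    regression extreme learning machine (SRELM), or t-SNE, and evaluates seven
    classifiers under five-fold cross-validation. Cluster quality of projected
    features is quantified by the separability index (SI), mean semi-principal
    axis (MSA), and repeatability index (RI), and a training-position-reduction
    experiment measures robustness to unseen limb positions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    MASS,
    e1071,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'emgrasp-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'featureset.R'
    'synthetic-data.R'
    'preprocess.R'
    'features.R'
    'projection.R'
    'classification.R'
    'metrics.R'
    'experiment.R'
    'cli.R'
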