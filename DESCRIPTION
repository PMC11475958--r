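Package: nircal
Title: NIR Moisture Calibration for Dried Seaweed Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Near-infrared (NIR) spectral calibration workflow for moisture
    content in dried laver (Porphyra yezoensis): seeded synthetic spectra
    generation with moisture-coupled absorption bands, Savitzky-Golay
    first-derivative preprocessing, SPXY/Kennard-Stone sample-set
    partitioning, genetic-algorithm wavelength selection with a
    cross-validated PLS fitness, gradient-boosted tree and one-dimensional
    convolutional/residual network regressors, Gaussian-process prediction
    intervals with a Matern 5/2 kernel, and the point/interval metric suite
    (R2, RMSEP, RPD, PICP, PINAW, CWC) with a six-run comparison report.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    xgboost,
    jsonlite,
    yaml,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'synthetic.R'
    'preprocess.R'
    'partition.R'
    'pls.R'
    'ga.R'
    'nn.R'
    'regressors.R'
    'gpr.R'
    'metrics.R'
    'report.R'
    'pipeline.R'
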