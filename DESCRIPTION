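Package: opsnir
Title: Ordered Predictors Selection and Successive Projections Workflows
    for Near-Infrared Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Chemometric calibration of analyte concentrations from
    near-infrared (NIR) diffuse-reflectance spectra. Implements NIPALS
    partial least squares (PLS1) and multiple linear regression with
    cross-validation, Kennard-Stone calibration/prediction partitioning,
    Monte Carlo prediction-error outlier screening, standard spectral
    preprocessing (mean centering, autoscaling, SNV, MSC, Savitzky-Golay
    smoothing and derivatives), ordered predictors selection (autoOPS,
    feedOPS, iOPS) driven by informative vectors (REG, COR, SQR, VIP, NAS,
    COV, URXY, WGHT), the successive projections algorithm (SPA), the
    usual evaluation statistics (R2, RMSEC/RMSECV/RMSEP, RPD, RER,
    SEP/SEC, relative errors), a synthetic FT-NIR spectra generator with
    known ground truth, and an end-to-end workflow driver with logged
    provenance. Spectra are held in a SpectraSet container extending
    SummarizedExperiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, tools, S4Vectors, signal, jsonlite
Suggests: testthat (>= 3.0.0), optparse, knitr, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'SpectraSet.R'
    'gram.R'
    'informative.R'
    'io.R'
    'metrics.R'
    'ops.R'
    'opsnir-package.R'
    'pls.R'
    'preprocess.R'
    'sampling.R'
    'spa.R'
    'synthetic.R'
    'utils.R'
    'workflow.R'
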