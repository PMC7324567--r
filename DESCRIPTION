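Package: cardioqsm
Title: Cardiac Quantitative Susceptibility Mapping from Multi-Echo Gradient-Echo MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantitative susceptibility mapping (QSM) of
    the heart from multi-echo gradient-echo MRI: Fourier-domain dipole forward
    model, multi-echo phase unwrapping and weighted least-squares field fitting,
    background field removal by projection onto dipole fields (PDF),
    morphology-enabled total-variation-regularized dipole inversion solved by
    iteratively reweighted least squares with conjugate gradients, voxelwise
    T2*/R2* relaxometry, and ROI/ROC analysis of infarcted versus remote
    myocardium. Includes a synthetic cardiac phantom generator (ellipsoidal
    myocardial shell with an infarct wedge) that synthesizes noisy complex
    echo series with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'utils-internal.R'
    'forward-model.R'
    'background-field.R'
    'cardioqsm-package.R'
    'field-prep.R'
    'io.R'
    'phantom.R'
    'roi-analysis.R'
    'relaxometry.R'
    'qsm-inversion.R'
    'pipeline.R'
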