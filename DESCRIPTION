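Package: drsclassify
Title: Diffuse Reflectance Spectroscopy Tissue Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a diffuse reflectance spectroscopy
    (DRS) tissue-classification workflow for discriminating prostate tumor
    from healthy tissue: white/dark reference calibration, two-spectrometer
    stitching onto a canonical 400-1600 nm grid, standard normal variate
    normalization, landmark (local extrema) and slope feature extraction from
    class mean spectra, from-scratch ReliefF feature ranking with top-20
    selection, and patient-wise repeated evaluation of a linear support
    vector machine with tenfold cross-validation, reporting sensitivity,
    specificity, accuracy and ROC/AUC with a Youden-optimal cutoff. Includes
    a synthetic chromophore-based spectra generator so every stage is
    testable without access to the original clinical measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
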