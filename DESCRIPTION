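Package: bonexcal
Title: Cross-Calibration of Dual-Resolution Bone Microarchitecture Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-calibrating bone microarchitecture outcomes between
    first- and second-generation high-resolution peripheral quantitative computed
    tomography (HR-pQCT) scanners. Provides synthetic bone phantom generation and
    dual-resolution scan simulation, Gaussian and Laplace-Hamming binarization,
    direct distance-transform morphometry (local thickness, spacing, porosity),
    bootstrap linear-regression cross-calibration, and percent-error and
    Bland-Altman agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    yaml,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
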