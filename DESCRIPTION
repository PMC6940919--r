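Package: bovivitals
Title: Contact-Free Vital Signs for Cattle from Video and Thermal Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating cattle vital signs without contact:
    KLT-style feature tracking with automatic detector selection and
    ratio-gated region-of-interest (ROI) reconstruction through video;
    eye-area and ear-base temperature extraction from radiometric
    thermal-infrared frames; respiration rate from periodic nostril
    pixel-intensity cycles in infrared video; heart rate from green-channel
    photoplethysmography via zero-phase Butterworth band-pass filtering and
    windowed FFT peak analysis at 0.5 s cadence; method-agreement statistics
    (normality checks, Pearson correlation, linear regression, bias,
    SD-based reference exclusion, per-animal/per-period aggregation); and
    seeded synthetic fixture generators with known ground truth for
    validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    nortest,
    png,
    Rcpp,
    signal,
    stats,
    tiff,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
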