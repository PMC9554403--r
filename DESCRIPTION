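Package: lusaer
Title: Quantifying Neonatal Lung Aeration from Lung Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify regional lung aeration at birth from lung
    ultrasound (LUS) cine clips, validated against computed-tomography (CT)
    air-fraction ground truth. Implements the ordinal LUS grading scale
    (types 0-3) with two-rater consensus, four quantitative image statistics
    computed on regions of interest below the pleural line (mean pixel
    intensity, coefficient of variation, and band-integrated Fourier power
    spectra parallel and perpendicular to the pleural line), voxel-threshold
    CT aeration measurement restricted to the superficial 1 cm of lung, and
    ordinary-least-squares regression models with 95% prediction intervals,
    log-linearization and stepwise backward elimination. A synthetic-data
    generator produces paired LUS clips and CT phantoms with known air
    fraction, airway pressure, inflation/deflation phase and grade, so every
    stage of the pipeline can be exercised and checked against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    RNifti,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
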