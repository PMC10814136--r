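Package: spectrareg
Title: Hyperspectral Regression and Wavelength Saliency for Fruit Quality
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Near-infrared hyperspectral workflow for non-destructive
    prediction of fruit internal quality (soluble solid content in degrees
    Brix, pH). Covers ENVI cube input with white/dark reflectance
    calibration, region-of-interest segmentation and mean-spectrum
    extraction, multiplicative scatter correction, box-plot outlier
    screening, PLSR-screened 3:1:1 dataset partitioning, seven calibration
    models (PLSR, SVR, 1-D CNN, LSTM, CNN-LSTM, Transformer encoder, and a
    CNN-Transformer hybrid trained with AdamW), R2/RMSE/RPD evaluation, and
    Grad-CAM wavelength-importance profiles. A synthetic hyperspectral
    generator with known informative absorption bands makes every stage
    testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    EBImage,
    graphics,
    grDevices,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
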