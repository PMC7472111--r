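Package: nitrospec
Title: Hyperspectral Estimation of Leaf Nitrogen Content
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for estimating leaf nitrogen content (percent of dry
    mass) from proximal hyperspectral measurements. Covers reflectance
    calibration of hyperspectral image cubes against dark-current and
    white-reference frames, detector splice-jump correction of point
    spectrometer signatures, Savitzky-Golay smoothing, leaf-bed detection via
    spectral-angle matching of a blue fiducial marker, leaf segmentation with
    hyper-hue features and a one-class support vector machine, spectral band
    resampling through Gaussian spectral response functions, partial least
    squares regression with cross-validated latent-variable selection and
    key-wavelength identification from averaged coefficients, and vegetation
    index baselines (narrow-band NDVI matrix and the normalised red edge
    area index). A synthetic-data generator with known ground truth emulates
    spectrometer signatures, camera cubes and sample ledgers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
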