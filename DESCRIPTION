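Package: stemborer
Title: Hyperspectral Grading of Striped Stem-Borer Infestation in Rice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end chemometrics pipeline for grading striped stem-borer
    (Chilo suppressalis) infestation of rice stalks into six ordinal degrees
    (DI0-DI5) from visible/near-infrared hyperspectral image cubes.
    Implements reflectance calibration against white/dark references, noisy
    band trimming, Savitzky-Golay spectral smoothing, region-of-interest mean
    spectra, successive projections algorithm (SPA) wavelength selection with
    MLR/RMSE subset choice, per-cube principal-component score images with
    gray-level co-occurrence matrix (GLCM) texture descriptors, Kennard-Stone
    calibration/prediction partitioning, min-max feature normalization and
    feature-level fusion, and a one-hidden-layer back-propagation neural
    network classifier. A synthetic hyperspectral scene generator emulates the
    six-class spectral and textural structure of infested rice stalks so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
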