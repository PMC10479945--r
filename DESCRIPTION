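Package: specsel
Title: Wavelength Selection Frameworks for Diffuse Reflectance Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discover small, physically interpretable subsets of
    illumination wavelengths for tissue classification from broadband diffuse
    reflectance spectroscopy (DRS). Implements a spectral preprocessing chain
    (repeat averaging, reflectance calibration, dual-spectrometer splicing,
    Savitzky-Golay smoothing), a one-versus-rest balanced-accuracy evaluation
    protocol with stratified cross-validation, and four wavelength-selection
    frameworks: principal component analysis with simulated-annealing subset
    search and eigenvector peak picking; moving-window linear discriminant
    analysis; backward interval partial least squares with vote aggregation
    over interval grids and CV shuffles; and an ensemble of univariate filters
    (mRMR, mutual information, ReliefF) refined by a shadow-feature random
    forest wrapper with SHAP-based explanation. A synthetic spectra generator
    with planted chromophore absorption bands provides recoverable ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    class,
    e1071,
    glmnet,
    ranger,
    xgboost,
    signal,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    mixOmics
Config/testthat/edition: 3
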