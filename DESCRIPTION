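Package: nmrshim
Title: Post-Acquisition Shimming of 1D NMR Spectra with a Convolutional
    Attention Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects lineshape distortions caused by residual magnetic-field
    inhomogeneity in 1D NMR spectra after acquisition. The spectrometer's
    distortion characteristics are learned from calibration measurements of a
    narrow singlet: a response function is extracted from each mis-shimmed
    calibration spectrum by least-squares deconvolution against the
    best-shimmed one, and a convolutional autoencoder with attention pooling
    is trained online on hybrid data (synthetic Lorentzian-Gaussian multiplet
    spectra convolved with measured response functions plus noise). A
    calibration simulator with a polynomial shim-field model makes the whole
    pipeline runnable and testable without a spectrometer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
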