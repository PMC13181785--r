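Package: nmrphaser
Title: Automated Phase Correction of 1D NMR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fully automated zeroth- and first-order (PH0/PH1)
    phase correction of one-dimensional solution NMR spectra. Provides a
    complex-spectrum data model with exact phase algebra, standard FID
    processing (apodization, zero filling, Fourier transform, digital-filter
    group-delay compensation), a synthetic-spectrum engine that generates
    labeled metabolomics-like training spectra with controlled phase errors,
    a classical entropy-minimization coarse phaser with an exhaustive
    two-dimensional grid search, a pair of sign-of-phase-error classifiers
    built from a strided convolutional front end and a transformer encoder
    with relative positional bias (implemented natively, with full
    backpropagation and Adam training), and an iterative correction loop
    that drives residual phase errors to sub-degree levels. Readers and
    writers for the Bruker 1D fid/acqus layout and JCAMP-DX are included,
    together with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
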