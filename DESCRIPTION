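Package: nirwave
Title: Maximum-Information Extraction from Overlapped NIR Spectra by
    Continuous Wavelet Transform
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Resolves heavily overlapped near-infrared (NIR) spectral bands by
    continuous wavelet transform (CWT) over a range of integer scales,
    collapses the scalogram into per-channel maximum and minimum coefficient
    channels, and uses the reconstructed signal for partial least squares
    (PLS) calibration. Factor counts are chosen by a leave-one-out PRESS
    ratio rule, the scale range by minimum calibration RMSE over a grid, and
    uninformative channels are eliminated by repeated UVE with a
    noise-derived stability cutoff. Includes fourteen mother wavelets, a
    synthetic generator for composite signals built from overlapping
    Gaussian sub-bands, CSV/MAT spectral IO and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Spectrometry, Regression, Preprocessing, FeatureExtraction
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'wavelets.R'
    'cwt.R'
    'reconstruct.R'
    'pls.R'
    'calibration.R'
    'uve.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
    'cli.R'
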