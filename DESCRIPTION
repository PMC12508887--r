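Package: ramanMQA
Title: Multivariate Semi-Quantitative Analysis of Single-Cell Raman
    Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for confocal Raman microspectroscopy of single cells:
    reading and writing hyperspectral cubes, wavenumber-axis calibration
    against a silicon reference, cosmic-ray removal, baseline correction,
    Savitzky-Golay smoothing and PCA denoising; compartmentalization by
    K-means clustering and endmember extraction with non-negative
    unmixing; univariate band-area imaging with internal-standard ratio
    normalization for semi-quantitative metabolite mapping; compartment
    statistics and calibration fitting.  Ships a curated metabolite band
    library for methanotroph-hosting bacteriocytes and a synthetic
    cell-phantom generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    data.table,
    jsonlite,
    yaml,
    signal,
    pracma,
    cluster,
    png,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
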