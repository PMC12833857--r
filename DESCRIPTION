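Package: vibmatch
Title: Vibrational Frequency Scaling and Spectral Similarity Matching
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping calculated harmonic vibrational frequencies
    onto experimental fundamentals and for identifying molecular conformers
    from measured Raman-type spectra. Derives global, range-dependent and
    mode-dependent empirical frequency scaling factors with uncertainties,
    computes the accompanying error statistics (RMS, mean absolute deviation,
    standard deviation, MAPE, quartiles) and runs randomized train/test
    resampling and intensity-stability protocols. Matches measured
    fundamental-band peak lists against scaled calculated spectra of
    candidate conformers using cross-correlation of Lorentzian-convolved
    spectra, Euclidean and Manhattan cost matrices with Kuhn-Munkres
    (Hungarian) minimal-cost assignment producing spectral barcodes, and
    one-dimensional optimal-transport (Wasserstein-1) distances, ranking
    candidates to identify the observed structure. Includes a synthetic-data
    generator emulating the statistical structure of curated fundamental-band
    databases so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
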