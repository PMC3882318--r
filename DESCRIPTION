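Package: NAcorrectR
Title: Multi-Isotope Natural Abundance Correction for Ultra-High
    Resolution FT-MS Isotopologue Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Removes the contribution of naturally occurring heavy
    isotopes from isotopologue peak intensities measured in stable
    isotope-resolved metabolomics (SIRM) experiments on ultra-high
    resolution Fourier transform mass spectrometers. Supports one, two
    or three simultaneous tracer isotopes (e.g. 13C, 15N, 2H) via an
    n-dimensional iterative deconvolution with non-negativity
    clamping, cached binomial correction tables, several numerically
    distinct binomial-term implementations for cross-checking, data
    quality control (count overflow, duplicate isotopologues,
    predicted-but-unobserved peaks), and configuration-driven
    processing of collection-scale delimited peak tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
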