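Package: ddex
Title: Double Diffusion Encoding, Water Exchange and Transient Kurtosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative diffusion MRI with double diffusion
    encoding (DDE) and variable mixing times. Constructs DDE gradient
    waveforms, rotation schemes and acquisition protocols; computes scalar
    and fourth-order-tensor exchange-weighting functions of a waveform;
    implements the correlation tensor imaging (CTI) and multi-Gaussian
    exchange (MGE, 1D-MGE, tMGE) signal representations that link microscopic
    kurtosis to intercompartmental water exchange and transient kurtosis;
    fits all representations to powder-averaged signals with bounded
    multi-start nonlinear least squares; and validates the whole chain with a
    Kaerger matrix-exponential oracle and a compiled Monte Carlo random-walk
    simulator supporting exchanging Gaussian pools and permeable restricted
    geometries (spheres, cylinders, beads).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
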