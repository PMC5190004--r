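Package: tilgrad
Title: Spatial Gradients of Tumor-Infiltrating Lymphocytes and Peritumoral Fibrosis
Version: 1.0.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies T-cell infiltration into solid tumors and peritumoral
    fibrosis from calibrated microscopy sections. Detects labeled cells by
    intensity thresholding and size filtering, computes cell density as a
    function of Euclidean distance from the outer tumor border in concentric
    bands, fits exponential-decay and linear models to the radial density
    profile and compares log-linear slopes between groups, measures collagen
    density in second-harmonic-generation and trichrome images with
    perimeter-error bounds, and estimates tissue volume from serial sections
    by the Cavalieri principle. Ships a synthetic-image generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
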