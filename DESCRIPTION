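Package: petalpol
Title: Imaging Polarimetry and Choice-Learning Analysis for
    Polarization-Patterned Artificial Flowers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying whether foraging insects can learn
    polarization patterns on artificial flowers. Implements
    rotating-analyzer Stokes imaging polarimetry (per-pixel angle and
    degree of linear polarization maps with degree-weighted false-colour
    rendering), preparation of linear camera frames (Bayer channel
    separation, dark-frame subtraction, translation registration),
    rendering of ground-truth-known analyzer stacks of bull's-eye
    polarizer targets, a constrained Latin-square trial randomizer, and a
    random-effects logistic learning-curve model fitted by per-subject
    Laplace approximation with nested-model comparison by change in
    deviance and AIC.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
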