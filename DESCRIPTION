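Package: evacount
Title: Absolute Nanoparticle Counting by Evaporated Volume Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaporated volume analysis (EVA) estimates the number
    concentration of a nanoparticle dispersion by evaporating a droplet of
    known volume on glass, imaging the dried deposit as an overlapping grid
    of micrographs, counting every diffraction-limited spot, and converting
    the count into particles per millilitre with a full uncertainty budget.
    The package implements the complete analysis chain: a ground-truthed
    synthetic micrograph generator, radial (pincushion) distortion
    calibration and correction, correlation-based tile stitching with a
    global least-squares layout, matched-filter spot detection with subpixel
    Gaussian fitting, nearest-neighbour statistics against complete spatial
    randomness, and Poisson counting metrology (detection and quantification
    limits, working range, coverage intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
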