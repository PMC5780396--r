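Package: bspim
Title: Biospeckle Light-Sheet Simulation and Automated Nematode Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for biospeckle selective plane illumination microscopy
    (BSPIM) of free-living nematodes in transparent soil. Provides a seeded,
    physics-based dynamic-speckle simulator (temporally decorrelating complex
    speckle fields under a scanned light sheet), the generalized-differences
    (GD) biospeckle activity index and a transect signal-to-noise metric,
    a 3D detection pipeline (8-bit conversion, boxcar background subtraction,
    anisotropic Gaussian smoothing, thresholded 3D connected-component
    counting), and evaluation utilities for count-recovery regressions and
    brightfield-versus-GD signal-to-noise comparisons. Results are returned
    as tibbles with tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    tiff,
    yaml,
    optparse,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
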