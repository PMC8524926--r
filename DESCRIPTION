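Package: crackdic
Title: Surface Crack Detection and Quantification by Digital Image Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Subset-based digital image correlation (DIC) for detecting and
    quantifying surface micro-cracks from speckle image pairs, motivated by
    the diagnosis of cracked tooth syndrome. Provides normalized
    cross-correlation subset matching with coarse-fine search and subpixel
    refinement, strain field estimation by windowed least-squares plane
    fitting, principal strain computation, crack localization by hysteresis
    thresholding and morphological skeletonization, and crack opening
    displacement estimation from rigid-body crack-face kinematics. A
    synthetic speckle image generator with analytic deformation fields
    (translations, affine warps, crack discontinuities) supplies ground
    truth for validation, and a command-line interface exposes the full
    simulate-match-strain-extract-quantify pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    igraph,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
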