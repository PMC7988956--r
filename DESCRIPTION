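Package: carposhape
Title: Statistical Surface and Averaged Bone-Density Modelling of the Carpal Scaphoid
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A desk-scale computational-anatomy pipeline for the carpal
    scaphoid. From calibrated density volumes and landmarked surface meshes it
    builds (a) a 3D statistical surface model via thin-plate-spline
    correspondence, non-scaling generalized Procrustes alignment and principal
    component analysis, with shape synthesis at +/- k SD and morphometric
    descriptors; (b) a 3D averaged volumetric bone mineral density model on an
    isotropic reference grid inside the mean shape, with concentric density
    zones and zone statistics; and (c) virtual cylindrical probing of candidate
    screw pathways. A synthetic phantom generator produces populations of
    two-lobed, waisted, bent ellipsoid bones with three concentric density
    zones and known generative parameters, so every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
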