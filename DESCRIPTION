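Package: osteoplan
Title: 3D Reconstruction of the Proximal Tibia from Biplanar Radiographs and
    Automated High Tibial Osteotomy Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for planning medial opening-wedge high
    tibial osteotomies from calibrated biplanar standing radiographs. The
    package generates synthetic two-leg lower-limb phantoms with known
    varus deformity and tibial slope, simulates EOS-style biplanar
    digitally reconstructed radiographs (parallel or moving fan-beam
    geometry), trains three convolutional networks (sagittal leg
    separation, heatmap landmark localization, and 2D-3D reconstruction of
    the proximal tibia) on a small native network core, triangulates joint
    centers, measures mechanical axis and tibial slope from the
    reconstructed surface, and searches the twelve-parameter osteotomy
    plan space with a multi-objective genetic algorithm.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
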