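Package: mosaicmech
Title: Photoreceptor Mosaic Image Analysis and Retinal Epithelial Strain Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of the zebrafish cone photoreceptor
    lattice mosaic and the planar mechanics of the retinal epithelium. Provides
    an ideal-lattice model of the adult cone mosaic with its neighbor rules and
    predicted reporter-profile ratios; a synthetic-data generator that renders
    confocal-like multi-channel z-stacks with a curved or tilted outer limiting
    membrane (OLM), glial band images, and laser-ablation recoil experiments
    with known ground truth; selective surface projection of z-stacks at the
    reconstructed OLM with tilt estimation; seeded watershed-style segmentation
    of apical cell profiles with reporter-intensity classification; steerable
    Gaussian-derivative ridge detection of oriented glial bands with
    FFT-based column-direction estimation; and strain estimation from tracked
    cell positions by affine least squares and polar decomposition, with
    Welch and unequal-covariance Hotelling group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse,
    withr
Config/testthat/edition: 3
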