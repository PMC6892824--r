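Package: nucseg3d
Title: 3D Nuclear Instance Segmentation with Synthetic Training Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end 3D instance segmentation of fluorescently labeled nuclei
    in microscopy volumes, trained entirely on synthetic data. Generates binary
    phantom volumes of randomly rotated ellipsoidal nuclei under a pairwise
    overlap cap, synthesizes plausible microscopy intensities from them (either
    with a classical degradation renderer or a spatially constrained CycleGAN
    trained on unpaired real volumes), trains a five-level 3D U-Net style
    encoder-decoder with a combined Dice and binary cross-entropy loss, separates
    touching nuclei with a quasi-3D orthogonal-plane watershed, and evaluates
    results with voxel-level (accuracy, Type-I/II error) and object-level
    (precision, recall, F1 under a 50 percent overlap rule) metrics. Includes an
    Otsu threshold plus 3D watershed classical baseline and tiled inference for
    volumes larger than one network input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
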