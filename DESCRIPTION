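Package: mrcnet
Title: Unsupervised Point Cloud Completion by Multi-Resolution GAN Inversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Completes partial 3D point clouds (for example LiDAR scans of
    plants or cartons) without paired supervision by inverting a pre-trained
    point-cloud generative adversarial network. A multi-resolution degradation
    mechanism -- an iterative farthest point sampling pyramid combined with a
    K-nearest-neighbour masking operator -- aligns generated complete shapes
    with the partial observation, and a multi-stage Chamfer reconstruction loss
    plus a multi-scale discriminator feature-matching loss drive joint
    optimization of the latent code and the generator parameters. Includes
    exact Chamfer/Hausdorff/F-score evaluation metrics, procedural carton and
    plant shape generators with LiDAR-like partial-scan simulation, XYZ/PLY
    input and output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    withr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
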