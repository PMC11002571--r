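Package: usformer
Title: Lightweight 3D Transformer U-Net for Left Atrium Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Single-stage volumetric segmentation of the left atrium in
    late gadolinium-enhancement (LGE) cardiac MRI with a lightweight
    U-shaped encoder-decoder whose two deepest stages are transformer
    stages built on transposed (channel-wise) attention. Provides the
    network and its purpose-built CPU compute backend, the combined soft
    dice + weighted binary cross-entropy training objective, in-plane
    affine augmentation, SGD training with cosine annealing, thresholded
    full-volume inference, spacing-aware 3D evaluation metrics (Dice,
    Hausdorff distance, average symmetric surface distance), NIfTI/NRRD
    volume input/output, and a seeded synthetic phantom generator that
    emulates the low-contrast, class-imbalanced, tubular-appendage
    character of atrial LGE scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
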