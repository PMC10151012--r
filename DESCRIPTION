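Package: frunet
Title: Fourier Channel Attention U-Net for Nuclei and Gland Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements FRUNet, a lightweight encoder-decoder segmentation
    network for biomedical images whose residual units are built from Fourier
    channel attention (FCA) blocks: per-channel attention weights are derived
    from the amplitude spectrum of the 2-D discrete Fourier transform of
    convolutional features and applied multiplicatively to the spatial
    features. Provides the combined binary cross-entropy plus Dice training
    objective, pixel-level evaluation metrics (Dice, mean IoU, recall,
    precision, F1), image/mask data loading with augmentation and
    deterministic k-fold splits, a seeded synthetic nuclei/gland image
    generator, structural and ablation model variants with parameter
    counting, and a fully seeded Adam training loop with a plateau
    learning-rate schedule. All layer forward and backward passes are
    implemented in the package, with the convolution core in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
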