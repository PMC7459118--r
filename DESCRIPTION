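Package: denseunet
Title: Dense U-Net Models for Slice-Wise Zonal Prostate Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs and trains the Dense-X U-net family of fully
    convolutional networks for slice-wise segmentation of the prostate
    gland and its central and peripheral zones on T2-weighted-like MR
    volumes. Provides volume I/O (NIfTI and MetaImage) with the fixed
    resample/crop/normalize preprocessing chain, a seeded synthetic
    prostate phantom generator, elastic and rigid data augmentation,
    cross-entropy, focal and soft-Dice training losses, a complete
    evaluation suite (Dice, relative absolute volume difference,
    Hausdorff and mean surface distance, sensitivity/specificity,
    regional apex/mid/base scoring, paired t-tests) and a k-fold
    cross-validation experiment harness. The convolutional engine
    (im2col convolutions, max pooling, strided transposed convolutions,
    softmax head, Adam optimiser with manual backpropagation) is
    implemented in C++ via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
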