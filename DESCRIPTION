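Package: irisynth
Title: Self-Supervised Iris Segmentation via Mask-Conditioned Image Synthesis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-supervised framework for iris image segmentation. An
    eleven-parameter anatomical model samples paired iris and periocular
    masks; a conditional adversarial network (U-Net generator, patch
    discriminator, L1-regularised objective) synthesises eye images from
    those masks; the mask/image pairs then train a fully convolutional
    segmentation network with no manual annotation, since every synthetic
    image carries the mask that conditioned it. Includes a procedural eye
    renderer so the whole pipeline runs end-to-end without external data,
    plus segmentation metrics (pixel accuracy, mean pixel accuracy, mIoU,
    frequency-weighted IoU) and the Frechet distance between embedded
    image sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    png,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, Segmentation, Visualization
RoxygenNote: 7.3.3
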