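Package: keratovae
Title: VAE-Augmented Deep Learning Screening of Keratoconus from Corneal
    Topography Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained, data-free pipeline for studying
    variational-autoencoder (VAE) image augmentation in keratoconus
    screening from color-coded corneal topography maps. Provides a
    parametric simulator of axial curvature maps (regular-astigmatism
    bowties for normal corneas; inferior-cone, central-cone and
    asymmetric-bowtie/skewed-radial-axis patterns for keratoconus), the
    image preprocessing chain (HSV cornea segmentation, structured-noise
    removal, order-preserving grayscale conversion), a convolutional VAE
    with the Gaussian reparameterization trick and Bernoulli
    reconstruction likelihood, latent-grid decoding and class-conditional
    dataset expansion, small CNN classifiers trained from scratch or via
    a frozen-then-fine-tuned transfer recipe, and clinical evaluation:
    confusion matrices, prevalence-adjusted predictive values, ROC/AUC
    with the sensitivity-equals-specificity cutoff, and Grad-CAM saliency
    maps. All neural-network forward and backward passes are implemented
    on top of base BLAS matrix operations, so the package runs on a plain
    CPU with no external deep-learning runtime.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
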