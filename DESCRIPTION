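Package: CipherLesion
Title: Privacy-Preserving Skin Lesion Classification with Block-Scrambling
    Encryption, Fused Convolutional Features and a Conditional VAE
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for privacy-preserving analysis of dermoscopy-like
    images. Implements a block-scrambling-based image cipher (block
    permutation, dihedral block transforms, negative-positive pixel
    inversion and colour-channel shuffling under four derived key streams)
    with exact decryption, reduced-scale convolutional feature extractors
    in the MobileNetV2, Inception and AlexNet styles with feature fusion,
    a conditional variational autoencoder classifier trained by
    backpropagation, the hippopotamus optimization metaheuristic for
    bound-constrained minimization and hyperparameter tuning, a
    confusion-matrix metric suite with macro averaging, and a download-free
    generator of labelled synthetic lesion images for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'CipherLesion-package.R'
    'rng.R'
    'raster.R'
    'keys.R'
    'partition.R'
    'bsbe.R'
    'metrics.R'
    'synthetic.R'
    'backbones.R'
    'fusion.R'
    'cvae.R'
    'hippo.R'
    'pipeline.R'
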