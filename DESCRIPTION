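Package: slicenet
Title: Multi-Slice Tensor CNN for iPSC-Derived Cell Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies microscopy images of induced pluripotent stem cells
    (iPSCs) and their derived lineages (mesenchymal stem cells, retinal
    ganglion cells, retinal pigment epithelium) with a five-branch
    "multi-slice tensor" convolutional network: one pooled whole-image branch
    plus four quadrant branches whose features are concatenated before a
    merge convolution. The trained network can be truncated at the flatten
    layer and used as a fixed feature extractor feeding a hybrid head
    (max-abs scaling, PCA to 512 dimensions, SVM), and the PCA coordinate
    along the axis separating the RPE and iPSC clusters provides an ordinal
    differentiation-degree score for iPSC-RPE images. Includes a synthetic
    phenotype image generator, flip augmentation and quadrant-expansion
    preprocessing, gradient-weighted class-activation heatmaps, and an
    end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    png,
    tiff,
    jpeg,
    EBImage,
    e1071,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
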