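Package: trichoseg
Title: Trichome Segmentation and Leaf Hairiness Quantification
Version: 0.1.0
Authors@R: person("trichoseg", "developers", role = c("aut", "cre"),
    email = "trichoseg@example.org")
Description: Toolkit for quantifying leaf hairiness (pubescence) from
    leaf-surface microscopy images. Provides a spline-based trichome
    annotation data model with sparse segmentation masks, a procedural
    generator of synthetic leaf images with ground-truth trichome splines,
    paired image/annotation augmentation (resize, random crop, random
    flip), a modular encoder-decoder convolutional segmentation network
    trained natively on the CPU, the Leaf Trichome Score (LTS, 1000 times
    the trichome-pixel fraction of an image), evaluation metrics (IoU,
    F1), aggregation across phenotyping metadata, LTS-based genotype
    ranking, and a grid-search harness over encoder, decoder, loss and
    augmentation choices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
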