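Package: leafseg
Title: Leaf Instance Segmentation with Modified One-Stage Segmentation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for instance segmentation of individual plant leaves in
    top-down rosette images. Implements the five standard evaluation measures
    for leaf instance segmentation (Best Dice, Symmetric Best Dice,
    foreground-background Dice and the signed/absolute leaf-count errors),
    readers and writers for indexed-PNG instance label maps, HDF5 containers
    and normalized polygon annotation text files, the joint image/polygon
    augmentation stack (HSV jitter, flips, random affine, four-image mosaic,
    random erasing), a seeded synthetic rosette generator, and three small
    one-stage segmentation networks - a C2f backbone with a path-aggregation
    neck, a variant with weighted bidirectional feature-pyramid fusion in the
    neck, and a variant with a Ghost (cheap-transform) convolution block in
    the backbone - trained with task-aligned assignment, distribution focal
    box regression and prototype-mask heads on the package's own array
    autodiff engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
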