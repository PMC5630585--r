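Package: starcut
Title: Star-Shaped Graph-Cut Segmentation of Hypoechoic Lesions in
    B-Mode Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Interactive, seed-based segmentation of hypoechoic liver
    lesions in 2-D B-mode ultrasound images. A circular template of
    radial rays is sampled around a user-defined seed point and turned
    into a directed graph whose minimum s-t cut yields a star-shaped
    closed contour; helper seeds placed on the lesion border pin the cut
    locally. The package also provides the evaluation metrics used for
    segmentation agreement studies (Dice similarity score, Hausdorff
    distance, perpendicular lesion diameters, two-way absolute-agreement
    intraclass correlation, bootstrap confidence intervals of medians),
    a synthetic speckle-phantom generator with known ground truth, and a
    batch evaluation harness that scores the segmentation pipeline on a
    deterministic phantom suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    igraph,
    EBImage,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'image_io.R'
    'radial_graph.R'
    'segmentation.R'
    'metrics.R'
    'phantom.R'
    'evaluate.R'
    'starcut-package.R'
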