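Package: grapeboost
Title: Grape Cluster Detection in Vineyard Images by Boosted Color-Component Classifiers
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects ripe grape clusters in RGB vineyard images for
    harvesting robots. Pixels are described by a small set of color
    components (HSI hue, YCbCr Cb, CIELab b*, and raw R/G/B averaged over a
    7x7 window); per-component linear weak classifiers are trained by an
    exhaustive lowest-classification-error search and combined into a strong
    classifier with discrete AdaBoost. The strong classifier sweeps the
    image, the binary result is cleaned by relative-size region filtering,
    disc opening/closing and hole filling, and clusters are reported as
    enclosing rectangles, with a barycenter split for two adjoining
    clusters. Includes the method's detection metrics (TPR/FNR/FPR,
    pixel recognition accuracy) and a synthetic vineyard-scene generator
    with ground-truth masks for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    jpeg,
    png,
    tiff,
    optparse,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
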