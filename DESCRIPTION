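Package: flockmetrics
Title: Crowding and Movement Indices for Broiler Flocks from Top-View Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computer-vision indices for precision-livestock monitoring of
    small broiler flocks with a ceiling camera. Reads 1 frame-per-second
    grayscale frame sequences, segments birds into blobs (low-pass
    filtering, background subtraction or global thresholding, morphological
    clean-up), and computes two group-level indices per frame: a cluster
    (crowding) index from blob area, perimeter, inter-centroid distance and
    blob count, and an unrest (movement) index in centimetres from the
    symmetric Hausdorff distance between consecutive-frame bird masks
    scaled by the camera's cm-per-pixel factor. Index series are averaged
    into 30-minute blocks and compared across temperature-by-enrichment
    conditions with a split-plot-in-time repeated-measures ANOVA and Tukey
    mean separation. A ground-truthed synthetic flock-scene simulator with
    regime presets supports end-to-end validation without animal video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    multcomp,
    Rcpp,
    rlang,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
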