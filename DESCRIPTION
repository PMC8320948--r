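Package: nesegment
Title: Nuclear Envelope Segmentation and Shape Modelling for Serial
    Block-Face SEM Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised segmentation of the nuclear envelope (NE) of
    single cells imaged by serial block-face scanning electron microscopy
    (SBF-SEM). Per-slice candidate nuclear regions are obtained from
    Canny edges, edge dilation, 8-connected superpixels and morphological
    filtering; a 3D nucleus is assembled by propagating accepted regions
    up and down from the central slice so that disjoint cross-sections
    near the nuclear poles are retained. Includes rigid inter-slice shift
    detection and correction by phase correlation, evaluation against
    ground truth with the Jaccard index and per-slice Hausdorff distance,
    and a spheroid shape model that ray-traces signed NE-to-spheroid
    distances onto a 2D longitude-latitude surface with summary metrics
    (mean, standard deviation, range, pixel ratios) and their
    correlations. A seeded phantom generator produces SBF-SEM-like
    stacks with exact ground truth for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
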