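Package: plaqglia
Title: Quantification of Amyloid Plaques, Plaque-Associated Glia and
    Neuroinflammation Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calibrated quantification of amyloid plaques and
    plaque-associated glial cells in multi-channel 2D confocal fields
    (threshold segmentation, DAPI-overlap cell positivity, physical-radius
    plaque dilation via the exact Euclidean distance transform), together
    with nCounter-style expression processing (negative-control background
    subtraction, geometric-mean housekeeping normalization, fold-change /
    ANOVA-Tukey differential-expression calling and a directional
    fold-change-reversal statistic) and group-comparison reporting.
    Includes seeded synthetic-data generators for ground-truth image scenes
    and grouped negative-binomial count matrices so every stage of the
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
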