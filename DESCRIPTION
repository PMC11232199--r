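Package: tmeseg
Title: Tumor Microenvironment Segmentation and Quantification for H&E Slides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An expert-in-the-loop pipeline for multiclass tissue segmentation
    of hematoxylin-and-eosin slide images and quantification of the tumor
    microenvironment in non-small cell lung cancer. Provides seeded synthetic
    pseudo-histology slides with exact ground truth, foreground segmentation
    and tiling with glass filtering, optical-density stain normalization, an
    iteratively refined random-forest pixel classifier, a multiclass U-Net
    trained on tiles, tumor-border delineation, tumor stroma/fibrosis/
    inflammation/vessel/necrosis/background ratios, Schwartz volume doubling
    times, and a tile-majority evaluation protocol with confusion matrices and
    weighted precision/recall/F1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    generics,
    randomForest,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    tiff,
    png,
    readr,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
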