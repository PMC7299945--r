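Package: ramanfnd
Title: Single-Scan Combined Photoluminescence/Raman Imaging of Cells and
    Luminescent Nanodiamonds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of single-scan confocal photoluminescence/Raman
    hyperspectral images of living cells incubated with fluorescent
    nanodiamonds (fNDs). Provides label-free nucleus visualization from
    region-specific C-H stretching-band intensity maps ("negative" and
    "positive" images), simultaneous detection and chemical localization
    of nitrogen-vacancy (NV) luminescent pixels by hierarchical two-means
    clustering (luminescence, C-H presence, brightness grade), classical
    k-means organelle segmentation of the fingerprint region for
    comparison, a seeded synthetic phantom generator with a calibrated NV
    emission model for validation, and image composition with the
    five-class color scheme.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
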