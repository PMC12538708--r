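Package: seedspread
Title: Spatial Uniformity Analysis for Single-Seed Spreading Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate and optimize the spatial uniformity of seeds
    spread on a conveyor belt for automated quarantine inspection of imported
    soybeans contaminated with ragweed (Ambrosia) seeds. Simulates seed-layout
    scenes under Poisson, hard-core and Thomas cluster point processes, renders
    them to RGB images with ground-truth masks, segments seeds by HSV color
    thresholding, bins binary masks into a grid of per-tile seed-pixel
    proportions, and scores uniformity with Moran's I under queen or rook
    contiguity weights, including a permutation null. Includes a Taguchi L18
    analysis (smaller-the-better signal-to-noise ratios, response tables with
    delta ranks, ANOVA, optimal-level selection), seed-counting verification
    metrics, and an end-to-end virtual spreading experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    EBImage
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
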