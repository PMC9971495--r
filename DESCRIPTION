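Package: fibredep
Title: Simulation and Image Analysis of Asbestiform Fibre Depositions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate, segment and quantify depositions of
    asbestiform (needle-like) particles on microscopy substrates. Simulates
    conventional evaporating-drop depositions (stain / coffee-ring effect,
    with bundle formation) and inkjet-style micro-drop grid depositions,
    renders calibrated grayscale images with ground truth, reproduces a
    standard segmentation workflow (smoothing, thresholding, connected
    components), measures per-object morphometry (area, minimum-area
    enclosing rectangle length/width, elongation factor), computes class
    histograms with per-square-millimetre normalisation, batch homogeneity
    statistics (mean, relative standard deviation, coverage, density), and
    automates NIOSH Method 7400 / AIA fibre-counting rules via
    skeleton-graph topology (crossed, branched and entangled objects).
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
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
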