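Package: stemdepth
Title: Non-Invasive Stem Diameter Measurement from RGB-D Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures maize stem diameter in the field from paired RGB and
    depth images without touching the plant. The pipeline segments the stem
    from the background in HSV colour space with Otsu thresholding, extracts
    a one-pixel centreline by two-subiteration thinning, intersects
    horizontal scanlines with the morphological-gradient contour,
    back-projects the edge pixels to 3-D with the pinhole model and the
    sensor depth, maps them between camera frames by rigid transformation,
    and reports the Euclidean chord as the diameter. Includes an evaluation
    suite (MAPE, MAE, RMSE, R-squared, Lin's concordance correlation,
    Wilcoxon signed-rank), a pinhole-imaging checkerboard baseline, a
    deterministic synthetic cylinder-scene renderer with exact ground truth,
    and readers/writers for 16-bit depth rasters, PLY point clouds and
    camera-parameter configs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tiff,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
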