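Package: trayvision
Title: Stereovision Phenotyping of Containerized Seedling Trays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Non-destructive growth phenotyping of containerized tree
    seedlings from top-view stereo RGB images. Segments foliage from the
    soil background inside a configurable cylindrical region of HSV color
    space and reports percentage greenness (green ground coverage);
    computes plant-masked block-matching disparity maps from rectified
    stereo pairs and converts them to millimetre-scale height maps using
    pinhole rig geometry; fits and evaluates allometric power-law and
    logarithmic growth models (RMSE%, BIAS%) linking height, greenness
    and biomass over time; and generates ground-truthed synthetic tray
    scenes and growth time-series so the whole pipeline can be exercised
    without cameras.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
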