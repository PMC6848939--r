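Package: phenotray
Title: Non-Destructive Plant Phenotyping from Overhead RGBD Imagery of
    Vertical-Farm Trays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to recover plant growth traits from a fixed overhead
    RGBD camera imaging seedling trays in a vertical farm. The pipeline
    merges consecutive depth frames, deprojects them to a metric point
    cloud through a pinhole camera model with radial undistortion,
    detects the tray cell grid with edge detection and a Hough
    transform, converts line-masked depth into a per-pixel plant height
    surface with per-cell statistics, projects leaf instance masks onto
    the point cloud, reconstructs each visible leaf as a triangulated or
    spring-relaxed quadrilateral mesh to measure its area, and predicts
    leaf weight from area through a leaf-density or small nonlinear
    regression model. An evaluation layer compares predicted and
    manually measured trait distributions with the Bhattacharyya
    distance, and a synthetic scene generator renders trays with full
    ground truth so every stage is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    RANN,
    deldir,
    matrixStats,
    nnet,
    yaml,
    jsonlite,
    png,
    EBImage,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
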