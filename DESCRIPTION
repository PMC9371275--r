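Package: curveprog
Title: Scoliosis Curve Measurement and Progression Prediction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for adolescent idiopathic scoliosis
    (AIS) curve-progression research: landmark-based radiographic
    morphometry (vertebral orientation from polygon moments, Cobb and
    wedge angles, spline-based apex detection), clinical feature encoding
    (bending flexibility, modified Lenke curve types, the eight-grade
    Risser "+" skeletal-maturity scale), a native implementation of
    sequential backward floating selection under cross-validated mean
    absolute error, random-forest regression of the final major Cobb
    angle with feature-importance ranking, and synthetic landmark and
    cohort generators with known ground truth for validating every stage
    without patient data.
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
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
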