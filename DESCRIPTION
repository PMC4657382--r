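Package: femcurve
Title: Three-Dimensional Morphometry of the Femoral Canal Curvature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the three-dimensional curvature of the femoral medullary
    canal from triangulated surface meshes. Implements a virtual osteometric
    board (two-stage gravity settling to a standardized anatomical frame),
    medullary-canal centerline extraction with inscribed-diameter profiling and
    isthmus detection, total-least-squares plane and three-dimensional circle
    fitting (radius of femoral curvature), the banking angle of the curvature
    plane relative to the coronal plane, an intramedullary-nail torus surrogate
    with cortex clearance checking, a sagittal three-section curvature analysis,
    and the cohort statistics used to relate these morphometrics to demographics
    (normality screening, group comparisons, Pearson correlation, collinearity
    diagnostics, p-to-enter/p-to-remove stepwise regression, and two-means
    sample-size calculation). A parametric synthetic-femur generator with exact
    ground truth makes every stage testable without patient imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    car,
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
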