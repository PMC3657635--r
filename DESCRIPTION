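Package: navdecode
Title: Combinatorial Decoding of Maze-Navigation Routes from Multivoxel fMRI Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers which route a navigator took through a complex virtual maze
    from region-of-interest fMRI activity patterns. Per-variable linear
    max-margin classifiers are trained under leave-one-trial-out
    cross-validation, their decision values calibrated into predicted
    probability traces with a four-parameter sigmoid, candidate tracks ranked
    by a sum-of-squares mismatch between predicted and actual variable traces,
    and rankings combined across information sources and brain regions by a
    performance-weighted average. Ships a complete synthetic testbed: a
    tile-map maze with doors, wall pictures and rewards, a route planner and
    kinematic track simulator, a ray-casting first-person renderer, extraction
    of the six behavioral/stimulus information sources (73 decoding
    variables), and an encoding-model generator of lagged, drifting, noisy
    voxel-by-TR signals including a non-informative white-matter control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    e1071,
    minpack.lm,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
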