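Package: rosepath
Title: Adaptive Picking-Path Planning for Selective Rose Harvesting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for turning per-image flower detections (rose blooms and
    buds, e.g. from a YOLO-style detector) into minimum-length picking tours.
    Implements a scene-complexity score built from target density and mean
    pairwise distance, a decision-tree gate that switches between a
    reciprocating (boustrophedon) traversal and a hybrid genetic algorithm
    with greedy seeding, elitism, tournament selection, adaptive mutation,
    2-opt local search and early stopping; baseline planners (nearest
    neighbour, ant system, brute force), a spatial point-pattern simulator
    for flower fields (uniform blooms, Thomas-clustered buds), a benchmark
    harness, and closed-form FLOP accounting for partial convolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
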