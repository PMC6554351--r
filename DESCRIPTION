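Package: gazeway
Title: Gaze Strategies for Waypoint Steering: Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how drivers direct their gaze while steering a
    winding path. Implements the geometry of an alternating half-circle track,
    a pinhole scene camera with pixel/visual-angle conversion and optical-marker
    homography estimation, a waypoint scheduler with constrained gap sampling,
    synthetic telemetry and gaze generators for contrasting predictive and
    reactive gaze strategies, penalized piecewise-linear gaze segmentation with
    saccade extraction, gaze time-headway estimation with a 3-degree trajectory
    exclusion, waypoint area-of-interest catch/crossover analysis, and the
    missing-waypoint saccade-vector analysis (Spearman correlations pooled via
    Fisher's z, Huber-loss line fits, paired t-tests with Cohen's d, exact
    binomial tests).
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
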