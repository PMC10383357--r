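Package: solwrite
Title: Markerless Scoring of the Sollerman Write-with-a-Pen Sub-Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts a black-and-white image of a straight-line shape into
    an interactive digital tracing target (Canny edge detection, probabilistic
    Hough line extraction, duplicate-segment merging), replays timestamped
    21-landmark hand frames through a frame-by-frame tracing state machine
    that enforces the tripod-pinch grip and a configurable drawing-radius
    tolerance, and assigns the Sollerman 0-4 performance score together with
    a hand-spasticity estimate (mean signed deviation of the drawing point
    from the shape). Includes a synthetic-fixture module that renders shape
    images with analytic ground truth and simulates tracing trajectories with
    controllable speed, tremor noise and failure events, so the whole system
    can be exercised without a camera.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    ggplot2,
    jsonlite,
    png,
    EBImage,
    rlang,
    generics,
    readr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    tiff
Config/testthat/edition: 3
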