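Package: dayspace
Title: Day-Level Activity-Space Exposure to Greenspace and Walkability and
    Accelerometer-Measured Physical Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for linking GPS-derived daily activity spaces to gridded
    built-environment layers and accelerometer-derived physical activity in
    intensive longitudinal designs. Builds time-weighted activity-space
    surfaces from 10-second GPS epoch streams (kernel density estimation,
    daily path area, and residential buffers), grids environmental source
    data (street-level greenspace, park proximity, park polygons, and a
    walkability index) to a common analysis grid, computes daily exposure
    metrics as time-weighted overlays, processes 10-second accelerometer
    count streams into day-level moderate-to-vigorous physical activity
    minutes with non-wear and valid-day rules, and fits random-intercept
    mixed models with within/between person-mean centering, intraclass
    correlation, effect modification, and simple slopes. Includes a
    synthetic-study generator with known ground-truth effect sizes so the
    whole pipeline is testable end to end without restricted cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
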