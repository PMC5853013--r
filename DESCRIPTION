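Package: bradykin
Title: Kinematic Indexes of Bradykinesia and Rigidity from Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of Parkinson's disease motor symptoms from
    wearable magneto-inertial recordings of UPDRS part III tasks (finger
    tapping, hand prono-supination, passive elbow rigidity). Extracts four
    kinematic indexes per recording: total task time, fatigability (slope of
    per-cycle peak-to-peak angular velocity), total spectral power of angular
    velocity, and movement smoothness (spectral arc length, SPARC). Includes
    zero-phase Butterworth band filtering, speed-profile cycle segmentation by
    a 10%-of-peak threshold, a synthetic-movement generator for all three
    tasks and cohorts (OFF / ON medication states and healthy controls), and
    the cohort statistical layer: Shapiro-Wilk screening, two-way
    repeated-measures and mixed-design ANOVA over medication state and sensor
    location, Bonferroni-corrected post hoc t-tests, and R-squared
    correlation against clinical UPDRS item scores.
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
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
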