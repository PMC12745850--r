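Package: nyctinast
Title: Schedule Simulation, Motion Quantification and Anticipation
    Statistics for Nyctinastic Plant Movement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing time-lapse recordings of nyctinastic
    (day/night) plant movement under programmable light-light-dark
    schedules. Builds and queries lighting schedules in which a day of
    length N hours is partitioned into dark (N/4), light (N/2) and dark
    (N/4) intervals; quantifies group-level plant motion as the mean
    absolute green-channel difference between successive frames; applies
    artifact-exclusion rules for lighting transitions, compressed-video
    key frames and watering events; aggregates motion into cycle by
    day-condition by time-of-day cells; computes the pre-light
    anticipation statistic and fits its logarithmic learning curve; and
    summarises designs with repeated-measures ANOVA including partial
    eta-squared. A synthetic-data module generates per-frame motion
    series and rendered image sequences with known ground truth so every
    pipeline stage is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
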