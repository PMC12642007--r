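Package: gazedominion
Title: Attention Analytics for AOI-Based Eye-Tracking Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing visual attention to
    static stimuli from screen-based eye tracking. Classifies raw gaze
    samples into fixations (velocity-threshold I-VT), assigns fixations to
    polygonal areas of interest (AOIs) under a category overlap-priority
    rule, and computes the standard per-AOI metrics: time to first fixation
    with right-censoring, fixation count, and total fixation duration
    (dwell). Provides first-hit distributions, benchmark summary tables,
    tie-aware pairwise dwell-dominance matrices with support masking and
    dominance scores, time-to-first-fixation precedence matrices, subgroup
    delta matrices, early-vs-sticky quadrant diagnostics with design-action
    heuristics, Gaussian gaze heatmaps, atlas-style figure panels, and a
    seeded synthetic-study generator with analytic ground truth for
    end-to-end testing.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mgcv,
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
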