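Package: sleepcourse
Title: Life-Course Segmentation of Reported Sleep Duration and Spatial
    Navigation Performance
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse self-reported sleep duration across the adult
    life-course in large mobile-game cohorts. Provides exact penalized
    piecewise-linear change-point detection on per-age mean curves (optimal
    partitioning with a brute-force oracle), trajectory-based wayfinding and
    training performance composites (path length, tutorial normalization,
    first-principal-component scoring, z-scaling), inclusion filtering and
    age-curve construction, Hedges' g effect sizes, a country random-intercept
    mixed-model stage with conditional modes, sleep-by-performance quadratic
    models per age group, country-cluster ANOVA with a label-shuffle
    permutation null, latitude/GDP country-level regressions, and a fully
    seeded synthetic cohort and trajectory generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
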