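Package: bodytyper
Title: Body-Shape Stratification and Aging Analysis for Anthropometric Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stratifying 3D body-scanner anthropometry into body types
    and studying their change with age. Scanner measures are height-normalized and
    Z-scored, aggregated into meta-measures (clusters of correlated measures),
    and used to cluster participants into body types that are compared against
    age-matched, sex-specific reference groups. Includes similarity-link inference
    of candidate aging transitions between body types, incidence and index
    trajectories by age, accelerometer wear-time validation, physical-activity and
    health-factor summaries, and a calibrated synthetic-cohort generator with
    block-correlated measures and a planted body-shape archetype mixture for
    testing every stage without access to restricted cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    class,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
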