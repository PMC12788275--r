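Package: frailtylog
Title: Frailty Assessment from Smartphone Digital Lifelogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating frailty in community-dwelling older adults
    from smartphone lifelog streams. Implements GPS-based usual gait speed
    extraction (activity-label filtering, temporal clustering, haversine
    instantaneous speeds, physiological speed banding, duration and radius
    quality control, moving-average smoothing), pedometer and accelerometer
    feature aggregation (daily and hourly step counts, 30-second chair-stand
    repetition counting), deficit-accumulation Frailty Index scoring from a
    configurable 50-item registry with missing-item denominator adjustment,
    and the associated statistical suite (Pearson correlations with Fisher
    confidence intervals, hierarchical regression with R-squared-change F
    tests, variance inflation factors, Huber robust regression, k-fold
    cross-validated R-squared). A synthetic cohort generator with a latent
    frailty factor and configurable planted effect sizes makes every stage
    testable end to end without access to the original cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    mgcv,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
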