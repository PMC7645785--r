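Package: propriomap
Title: Hand Localization Error Maps: Simulation, Idiosyncrasy Statistics, and Person Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing spatial maps of proprioceptive hand-localization
    error measured on a grid of visual targets. Includes a seedable synthetic-cohort
    simulator (smooth idiosyncratic vector fields, shared group bias, session-wise
    learning shrinkage, trajectory-matching movement traces), construction of
    per-subject per-session error maps with regional and directional summaries,
    exact binomial direction-bias tests, within- versus between-subject similarity
    statistics (Pearson correlations with Fisher's Z, scaled Euclidean distances,
    Kendall's W trend tests), a small convolutional neural-network classifier for
    person identification from error maps, trajectory-matching motor-error scoring
    (interpolated cut-point RMSE, endpoint error, trajectory-local localization
    error, subject-dummy regression), and a seeded end-to-end pipeline with CSV,
    JSON and YAML interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
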