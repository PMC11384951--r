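Package: sofaspace
Title: State-Space Quantification of Therapeutic Drug Monitoring Benefit in Sepsis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the benefit of therapeutic drug monitoring (TDM) in
    septic ICU patients as a "multidimensional SOFA" state-space analysis: each
    patient-day state vector's Mahalanobis distance to the empirical SOFA = 1
    reference distribution is aggregated per treatment arm and day and
    normalized by the reference group's mean pairwise distance. Includes a
    synthetic two-arm longitudinal cohort simulator with latent organ-dysfunction
    dynamics, a data-preparation pipeline for heterogeneous clinical records
    (daily aggregation, unit harmonization, imputation, pathogen binarization),
    leakage-safe target encoding and standard scaling, a genetic-algorithm
    wrapper for feature selection with repetition frequency analysis, and the
    accompanying distribution and outcome statistics (two-sample
    Kolmogorov-Smirnov statistic, Hellinger distance, exit curves, two-factor
    Type-2 ANOVA on last-recorded SOFA scores).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    car,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
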