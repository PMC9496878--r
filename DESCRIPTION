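Package: dynstab
Title: Temporal Stability of Dynamic Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sliding-window dynamic functional-connectivity networks
    from region-of-interest fMRI time series, binarises them over a grid of
    proportional connection densities, and quantifies their temporal
    stability with the nodal temporal correlation coefficient, aggregated
    to functional-network and whole-brain level. Includes the
    covariate-adjusted group-comparison and clinical-correlation statistics
    used in case-control resting-state studies (ANCOVA with
    Benjamini-Hochberg correction, Spearman and partial Spearman
    correlations, proportional-odds models), and a synthetic-cohort
    generator with hidden-state covariance switching so the whole pipeline
    can be exercised and validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
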