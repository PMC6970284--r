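Package: t1zmap
Title: Z-Score Mapping and Reference Ranges for Cardiac MOLLI T1 Parametric Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardizes cardiac MOLLI (Modified Look-Locker Inversion
    recovery) native T1 parametric maps across scanner platforms by
    pixel-wise Z-score transformation against platform-specific healthy
    reference statistics. Provides synthetic short-axis phantom cohorts
    with known ground truth, myocardial contour rasterization with
    transmural-depth based exclusion of the outer subendocardial and
    subepicardial layers, a per-platform reference-statistics database
    with (mean - 2SD, mean + 2SD) normal ranges, integer (x100) Z-map
    storage with diverging-palette rendering, and the accompanying cohort
    statistics suite: normality and variance-homogeneity checks, classic
    and Welch one-way ANOVA with Bonferroni post-hoc, independent
    t-tests, TOST equivalence testing, and normal-range classification
    with sensitivity and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    nortest,
    png,
    purrr,
    rlang,
    scales,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
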