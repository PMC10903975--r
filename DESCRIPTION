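Package: objscd
Title: Actuarial Classification and Voxel-Wise Centrality Mapping for Subtle Cognitive Decline Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying resting-state functional-connectivity centrality in
    objectively-defined subtle cognitive decline (Obj-SCD). Implements actuarial
    neuropsychological classification (regression-based norms on a robust normative
    sample, AVLT process scores, Obj-SCD and MCI decision rules, CSF amyloid
    stratification), a BOLD time-series cleaning chain (volume discard, Power
    frame-wise displacement, Friston-24 nuisance regression, band-pass filtering),
    voxel-wise degree and fast eigenvector centrality mapping, and group inference
    (summary-statistic ANOVA, chi-square, voxel-wise ANCOVA with permutation-based
    cluster-level correction, Fisher LSD post hoc tests, partial correlation, and
    two-timepoint repeated-measures interaction tests). A synthetic cohort generator
    produces phenotype tables and 4D BOLD phantoms with planted group structure for
    end-to-end validation.
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
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
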