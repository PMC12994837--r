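Package: concordkit
Title: Concordance, Missingness, and Prevalence Sensitivity for Linked
    Demographic Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the quality of race and ethnicity
    information across linked administrative records, modelled on linked
    electronic health record (EHR) and census microdata analyses.
    Harmonizes heterogeneous source codings to the 1997 OMB categories,
    resolves multiple census-style observations per person by allocation
    filtering, conflict dropping, and source/recency priority, classifies
    per-person concordance, partial concordance, discordance, and
    nonreporting, collapses clinical codes to 3-digit ICD-10 outcome
    groups, and quantifies how the choice of labeling source shifts
    group-level outcome prevalence estimates (continuity-corrected Wilson
    intervals, delta-method shift intervals from clustered logistic fits,
    Bonferroni family-wise adjustment). Includes a fully parameterized
    synthetic linked-cohort generator with closed-form expected rates, and
    a discrete Gaussian count-noise mechanism for disclosure-style output
    protection.
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
    purrr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
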