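Package: kanosurvey
Title: Kano-Model Demand Analysis for Paired Likert Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing service-demand surveys built on the Kano
    model of quality attributes. Classifies paired functional/dysfunctional
    five-level Likert responses with the standard Kano evaluation table,
    tabulates per-attribute category counts, and derives final category,
    category strength, total strength and the Better/Worse
    satisfaction/dissatisfaction coefficients. Includes Better-Worse quadrant
    plots, rank-sum comparison of category distributions between respondent
    groups, survey CSV reading with validity filtering, a seedable synthetic
    respondent generator with exact reconstruction from published category
    counts, and bundled summary tables from a telenursing demand study of
    empty-nest elderly individuals with chronic diseases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
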