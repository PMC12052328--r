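Package: novascore
Title: Food-Processing Knowledge Score (Nova-Conhecimento): Scoring and
    Validity Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Nova-Conhecimento food-processing knowledge
    score, a 12-item instrument in which respondents rate the healthiness
    of foods from four categories on a 1-10 scale and knowledge is scored
    0-8 from how well within-category ratings recover the Nova ordering
    (unprocessed > processed > ultra-processed). Provides the bundled
    instrument definition, ranking-based scoring with explicit tie and
    missing-data policies, a synthetic-data generator for respondents and
    repeated 24-hour dietary recalls, a variance-components shrinkage
    estimator of usual ultra-processed food intake, and the discriminant-
    and convergent-validity statistical battery (Mann-Whitney comparison,
    group-comparability tests, covariate-adjusted linear regression, and
    nonparametric sample-size planning).
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
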