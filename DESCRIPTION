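Package: chronoeat
Title: Temporal Eating Patterns and Food Choices from Timestamped Food Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing timestamped free-text food and beverage
    logs collected by smartphone diary apps. Implements free-text item
    parsing against typed food dictionaries with typo correction,
    compliance filtering with delayed-log and backlog detection,
    chrononutrition metrics (eating occasions, TF50, average and 95%
    eating windows, day-to-day first/last intake shifts), dietary
    diversity, popularity and habituality statistics, subgroup
    comparison via Jensen-Shannon distance permutation tests and
    nonparametric effect sizes, hierarchical clustering of diurnal
    consumption profiles, and a seeded synthetic-cohort generator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
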