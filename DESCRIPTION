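Package: rbfood
Title: Risk-Benefit Assessment of Food Substitution Scenarios in Dietary Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for low-tier dietary risk-benefit assessment of food
    substitution scenarios in short-term recall surveys. Replaces a stated
    fraction of regular foods with replacement foods (e.g. seaweed-derived
    analogues of pasta, bacon and lettuce), maps consumed foods to substance
    concentrations through a hierarchical food classification with fallback
    to aggregated parent-level means, handles left-censored occurrence data
    (half LOD/LOQ imputation) and dry-to-wet weight conversion, estimates
    chronic usual intake of nutrients (iodine, sodium) and exposure to
    contaminants (arsenic, cadmium, lead, mercury) with a two-part
    logistic-normal-normal model fitted to repeated 24-h recalls, and
    characterizes the resulting distributions against health-based guidance
    values and benchmark-dose reference points (margins of exposure,
    exceedance fractions, traffic-light classification). Includes a
    synthetic survey generator with known ground-truth usual-intake
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
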