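Package: raschkit
Title: Classical Test Theory and Rasch Measurement for Educational Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for routine psychometric analysis of
    person-by-item score matrices: classical test theory item analysis with
    customizable flagging, dichotomous Rasch and partial credit models
    estimated by marginal maximum likelihood, Wright-map and Thurstonian
    threshold diagnostics, many-facets differential item functioning,
    fixed-anchor test equating across linked forms, one-way ANOVA on person
    ability, and inter-rater intraclass correlation. Results are collected in
    a fixed 13-sheet workbook layout with a conditional narrated report, and a
    synthetic-data module generates dichotomous, partial-credit, grouped, and
    linked-form fixtures for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    emmeans,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
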