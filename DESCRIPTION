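Package: sidesearch
Title: Differential Effect Subgroup Search for Group Health Inequalities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recursive-partitioning search for subgroups ("social
    locations") of a survey population where the gap in a health outcome
    between two contrast groups significantly exceeds the overall gap.
    Implements a centered variant of Subgroup Identification based on
    Differential Effect Search (SIDES): candidate binary splits of each
    covariate are scored by a two-child normal criterion on subgroup
    statistics centered at the whole-sample gap, covariates are ranked
    after a per-covariate multiplicity adjustment, the search recurses to
    a bounded rule depth under a continuation criterion, and discovered
    subgroups receive permutation-based adjusted p-values. Includes a
    calibrated synthetic generator for adolescent-survey-like data with
    known planted gender-by-subgroup interactions, Table-1-style
    descriptive summaries, broom-style tidiers, forest-plot methods, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
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
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
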