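Package: dyadkit
Title: Actor-Partner Interdependence Models for Distinguishable Dyads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dyadic analysis of couple data with the Actor-Partner
    Interdependence Model (APIM) for distinguishable dyads, estimated by
    maximum-likelihood covariance-structure fitting. Fits the saturated
    APIM in closed form from raw one-row-per-dyad tables or directly from
    published summary statistics (means, SDs, correlation matrix, n),
    tests equality constraints on actor and partner paths by chi-square
    difference tests, and provides the surrounding toolkit: PHQ-9 and core
    FertiQoL questionnaire scoring, paired comparisons and correlation
    reports from raw data or summary moments, Cronbach's alpha, moment-
    matched synthetic dyad generation, and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
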