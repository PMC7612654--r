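Package: latentpower
Title: Power and Sample Size for Mixed-Outcome Co-Primary, Multiple
    Primary and Composite Endpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Power calculation, sample-size estimation and empirical
    verification for clinical-trial endpoints that combine continuous,
    ordinal and binary outcomes under a latent multivariate-normal
    (probit-threshold) model. Supports co-primary (intersection)
    endpoints via multivariate-normal orthant probabilities, multiple
    primary (union) endpoints with Bonferroni or Holm multiplicity
    adjustment and analytic or simulated family-wise error rates, and
    composite responder endpoints with delta-method variances derived
    from a latent model fitted to pilot data. Includes a seeded
    synthetic-trial generator for empirical power studies.
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
    mvtnorm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
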