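Package: fpest
Title: Bayesian Hierarchical Estimation of Contraceptive Prevalence and
    Unmet Need for Family Planning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates and projects family-planning indicators (contraceptive
    prevalence by method type, unmet need, total demand, and demand satisfied
    by modern methods) for women of reproductive age, separately for married
    or in-union women (MWRA) and unmarried women (UWRA), from compilations of
    national survey estimates. Country-year trajectories combine logistic
    growth trends with stationary AR(1) deviations on transformed scales and
    are fitted jointly in a Bayesian hierarchical model (via JAGS) that
    borrows strength across a geography hierarchy, with an additional
    sexual-activity grouping for unmarried women, survey-bias and
    source-type nonsampling-error terms, probabilistic projection to 2030,
    and count-scale aggregation to all women of reproductive age. Includes a
    synthetic-data generator, cross-validation and parameter-recovery
    tooling, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
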