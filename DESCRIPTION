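Package: plhivmeta
Title: Comparative Frequentist and Bayesian Meta-Analysis of Severe
    COVID-19 Outcomes in People Living with HIV
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Random-effects meta-analysis of severe COVID-19 outcomes among
    people living with HIV with age-associated comorbidities, comparing a
    classical frequentist analysis (DerSimonian-Laird between-study variance,
    Cochran's Q, I-squared, Q-profile confidence intervals for tau) with a
    Bayesian normal-normal hierarchical model using half-normal or half-Cauchy
    heterogeneity priors, an improper uniform prior on the pooled effect, and
    deterministic quadrature over the heterogeneity parameter. Provides
    posterior, predictive and per-study shrinkage summaries, prior sensitivity
    analysis, publication-bias diagnostics (Begg-Mazumdar rank correlation and
    a mixed-effects Egger-type regression), log odds-ratio computation from
    2x2 tables, CSV input/output, a binomial two-arm study simulator for
    calibration experiments, and the embedded per-study effect table of the
    underlying evidence base.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
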