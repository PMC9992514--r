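Package: trop
Title: Transformer-Based Forecasting of County-Level Opioid Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for forecasting yearly county-level opioid death rates
    from past mortality and aggregated social-media topic features. The
    pipeline reads county-year mortality, topic-loading and socio-economic
    tables, age-adjusts crude rates via within-year regression residuals,
    imputes and reduces topic vectors with non-negative matrix
    factorization, differences the series, and fits a small from-scratch
    multi-head self-attention sequence model alongside bidirectional
    gated recurrent networks, ridge autoregression and heuristic
    baselines. Includes the evaluation protocol (MAPE, MAE, paired
    t-tests, per-year breakdowns), a lagged topic-change association
    analysis with Benjamini-Hochberg false-discovery control, and a
    seeded synthetic county-panel generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
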