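Package: heatlag
Title: Distributed-Lag Nonlinear Models for Temperature and Daily Injury Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-series analysis of daily event counts against extreme
    environmental temperature: natural cubic spline cross-bases for
    exposure-lag-response surfaces, quasi-Poisson regression with
    Pearson-dispersion inference, minimum-risk temperature (MMT) estimation,
    relative risks at percentile contrasts over lags 0-3, attributable
    fraction and number with Monte Carlo empirical confidence intervals,
    added heat-wave effects under a catalog of percentile/absolute
    definitions, and thermal-stress indices (Humidex, WBGT, apparent and
    effective temperatures). Includes a seeded synthetic weather and count
    generator with closed-form ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
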