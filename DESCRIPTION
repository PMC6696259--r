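Package: bloomindex
Title: Phytoplankton Bloom Detection from Satellite Absorption-Coefficient Baselines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-site monthly climatological baselines from daily
    satellite absorption-coefficient time series (phytoplankton absorption
    aphy and detritus-plus-CDOM absorption adCDOM, in 1/m), computes an
    eigenvector-weighted standardized-anomaly index (the IOP index) for each
    day, classifies days into non-bloom, pre-alert and active-bloom states
    with a conservative hold rule across cloud-cover gaps, and summarizes
    interval frequencies, annual exceedance, run-length persistence, trend
    splits, absorption-contribution fractions and field-versus-satellite
    rank-correlation validation. Includes a calibrated synthetic-data
    generator (correlated daily series, cloud-gap missingness, injected
    bloom events with ground truth) so the whole pipeline is testable
    without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2,
    withr
Config/testthat/edition: 3
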