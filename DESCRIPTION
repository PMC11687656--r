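Package: dielmetab
Title: Stream Metabolism from Diel Dissolved-Oxygen Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Single-station estimation of stream ecosystem metabolism from
    high-frequency dissolved-oxygen logger records.  Provides a forward
    model of diel dissolved-oxygen dynamics (gross primary production,
    ecosystem respiration and atmospheric reaeration), per-day Bayesian
    estimation of the metabolic parameters with posterior-predictive
    quality control, a seeded synthetic-scenario generator for seasonal
    sensor campaigns, and downstream analytics: seasonal summaries and
    trophic classification, Arrhenius (metabolic theory of ecology)
    temperature fitting of respiration, light-temperature regression of
    primary production, rank-correlation screening, oxygen-saturation
    diagnostics and hypoxia-risk classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
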