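Package: pollenscape
Title: Trait Matching, Pollen Transfer and Landscape-Scale Pollination in
    Nectar-Feeding Birds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify plant-pollinator trait matching and its
    consequences for pollen transfer and feeding efficiency in nectarivorous
    birds, built around a honeyeater-emu bush (Eremophila maculata) study
    system. Computes bill-corolla matching ratios and reduces them to
    multivariate matching scores by principal component analysis; converts
    high-speed-video measurements (anther-contact frames, feeding-bout frames,
    lick counts, digitized pollen-patch polygons) into per-visit transfer and
    feeding metrics; fits the corresponding generalized linear mixed models
    (negative binomial, Tweedie and Gamma families with log links, optional
    zero inflation, type-III Wald tests, Tukey-adjusted pairwise contrasts,
    Cohen's d, and trigamma-method marginal and conditional R-squared); and
    scales per-flower pollen deposition to plant-visit and landscape totals by
    resampling measured deposition values onto camera-trap visitation records.
    A synthetic-data generator with the statistical structure the analysis
    assumes makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmmTMB,
    car,
    emmeans,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
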