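Package: foodrisk
Title: Macro-Level Food-Insecurity Risk Ranking of Countries
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A three-stage pipeline for ranking countries by macro-level
    food-insecurity risk from health-economic indicators. Stage one reduces
    GDP per capita, GDP growth rate, and per-capita health spending to a
    single principal-component factor with regression-method factor scores
    and Bartlett's sphericity test. Stage two embeds six food-insecurity
    criteria together with the factor in two dimensions by metric SMACOF
    multidimensional scaling and converts each criterion's distance to the
    factor into a criterion weight. Stage three ranks countries by TOPSIS
    (Technique for Order of Preference by Similarity to Ideal Solution)
    with benefit/cost criterion directions. Ships a 14-country OECD 2020
    reference dataset, a single-latent-factor synthetic data generator, and
    report writers for every intermediate product.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
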