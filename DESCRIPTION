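Package: seslt
Title: Socioeconomic County Life Tables and Cancer Relative Survival
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds period life tables that capture county-level
    socioeconomic and geographic variation in background mortality, and
    measures their impact on cancer survival statistics.  Mortality rates
    for ages 30-84 are smoothed with Poisson regression on restricted cubic
    splines of age and calendar year, with SES-quintile main effects and
    SES-by-age interactions; the modeled rates are extended to ages 0-99 by
    borrowing the age shape of a reference life table anchored at ages 35
    and 84, and summarized as truncated life expectancy.  Companion tools
    compute Ederer II expected survival, relative survival and
    cause-specific survival for patient cohorts matched to the tables, and
    a synthetic-data generator with a known mortality surface and excess
    hazard makes every stage testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
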