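Package: shelf2serves
Title: Dietary Indicators and Reports from Store Point-of-Sale Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts weekly store point-of-sale records into key dietary
    indicators aligned with the Australian Dietary Guidelines: serves of the
    five food groups and of discretionary ("Unhealthy") foods purchased per
    person per day, energy-normalised to a reference daily energy requirement
    of 8.9 MJ. Links sales to a flat food-composition reference, derives
    population-weighted guideline targets from demographic strata, computes
    comparator series (all-store average, targets), and renders deterministic
    HTML reports with gauge and trend charts and traffic-light healthiness
    colouring. Includes a synthetic point-of-sale generator with known
    ground-truth indicator values so the whole pipeline is testable without
    restricted sales data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    lubridate,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    glue
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
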