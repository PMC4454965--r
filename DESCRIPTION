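Package: heatstrain
Title: Population-Level Simulation of Human Heat Strain Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state human heat-balance simulation (a MANMO-style
    man model) scaled to a national population of weighted person-types.
    Computes individual heat storage from weather (air temperature,
    humidity, solar radiation, wind) and individual characteristics
    (body surface area, maximal sweat rate, metabolic rate), then
    aggregates over age-sex strata discretized by height, mass, sweat
    rate, occupation-derived exertion, and weather exposure to report
    the proportion of each age-sex group gaining 2 degrees Celsius or
    more of body heat per hour. Includes a seeded synthetic generator
    of population, occupation, and summer weather tables, built-in
    extreme city-day weather fixtures, and CSV/JSON reporting with
    stacked-bar and time-series figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
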