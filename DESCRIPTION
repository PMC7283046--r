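Package: beefcarbon
Title: Cradle-to-Farm-Gate Carbon Footprinting of Beef Farming Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A whole-farm greenhouse-gas accounting engine for beef
    production systems. Computes annual emission inventories (enteric
    methane via IPCC tier-2 or per-head tables, manure methane and nitrous
    oxide, soil and indirect nitrous oxide, liming, fuel and embedded
    off-farm emissions), aggregates them to CO2 equivalents under GWP100,
    and reports gross and net carbon footprints per unit of live-weight
    gain, live weight sold and carcass weight. Region-flavoured
    emission-factor sets are pluggable; a comparison harness quantifies
    between-model footprint differences and ranking concordance, and a
    mitigation-scenario engine applies single measures or stacked plans
    and evaluates them against a footprint-reduction target. Includes a
    deterministic generator of synthetic case-study farm archetypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    readr,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
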