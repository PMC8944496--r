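Package: flockfoot
Title: Whole-Farm Greenhouse Gas and Nutrient Footprint Simulation for
    Dairy Sheep and Goat Farms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An empirical whole-farm simulation model for dairy small-ruminant
    systems (autochthonous and foreign dairy sheep breeds and dairy goats).
    Couples printed regression sub-models for herd demography, excreta and
    winter-cereal forage yield with Tier-2 enteric methane (Ym from diet
    digestibility), manure and soil ammonia/nitrous-oxide cascades, embedded
    carbon dioxide of purchased inputs, and soil carbon sequestration.
    Reports carbon, water, energy and nitrogen footprints plus acidification
    and eutrophication potentials over four functional units (hectare,
    livestock unit, present female, liter of fat- and protein-corrected
    milk), farm-gate nitrogen and phosphorus balances, a mitigation-scenario
    engine, seeded synthetic-farm generators, and the Nash-Sutcliffe /
    Willmott model-validation battery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    lmtest,
    optparse
Config/testthat/edition: 3
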