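Package: thermaffin
Title: Occupancy-Derived Thermal Affinities of Marine Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives species-level thermal affinities by matching marine
    occurrence records (latitude, longitude, depth, date) to gridded sea
    temperature products: a surface/bottom climatology and a depth- and
    month-resolved gridded field on World Ocean Atlas standard depth bands.
    Aggregates experimental upper thermal limits (CTmax, LT50, LT0/LT100),
    fits second-order polynomial models of thermal limit against affinity
    with functional-group structure and nested F-tests, and computes thermal
    safety margins with temperature-affinity binning. Includes a seeded
    synthetic-ocean generator (gridded temperature fields, occurrence tables
    with realistic data defects, thermal-limit records with known generating
    parameters) so the full workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
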