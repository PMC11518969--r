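Package: linksim
Title: Individual-Based Demographic Microsimulation for Entity-Resolution Research
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a population of individual agents ("simulants") living in
    households and group quarters, evolving on a 28-day clock through mortality,
    fertility (with twinning), domestic and international migration, and
    employment dynamics. Identity attributes (names, Social Security Numbers,
    ITINs, employer names generated by bigram-multigraph random walks) are
    attached to simulants, and dataset observers emit simulated decennial
    census, tax, WIC, and household-survey records carrying ground-truth
    simulant identifiers, producing linked record sets for benchmarking
    entity-resolution methods. All calibration inputs (microdata, hazard-rate
    tables, name frequency tables, a business-name corpus, an address lexicon)
    are generated by a bundled synthetic-fixtures module, so the simulator runs
    with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
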