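Package: droughtscreen
Title: Drought-Tolerance Screening of Cultivar Panels from Wilting,
    Recovery and Water-Content Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate drought tolerance across a panel of crop
    cultivars from plant-level phenotyping records. Computes relative water
    content (RWC) from fresh/turgid/dry weight triples, a radar-chart
    drought-tolerant index (DTI) from interleaved wilting and recovery
    percentage time courses, classifies cultivar trait means against
    published length and dry-matter thresholds, and compares cultivars with
    a from-scratch one-way ANOVA followed by Duncan's multiple range test
    with compact letter display. Ships a synthetic-panel generator with a
    known latent tolerance per cultivar so the whole pipeline can be
    exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
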