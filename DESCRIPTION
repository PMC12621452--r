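Package: aquanrf
Title: Nutrient Density and Affordability Profiling of Aquatic Foods
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nutrient Rich Food (NRF) profiling of fish and shellfish
    composition data expressed per 100 g edible portion: percent-daily-value
    scoring with capping, NRF6.2 and aquatic NRF9.2 indices, hierarchical
    lookup imputation with provenance tracking, edible-portion price
    processing and an NRF affordability index, one-way ANOVA with Tukey HSD
    compact-letter displays, and a seeded synthetic-data generator that
    emulates the group structure of the FAO/INFOODS uFISH database so the
    whole pipeline runs without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
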