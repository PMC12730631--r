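Package: zooniche
Title: Functional Groups, Niche Metrics and Interspecific Association for
    Zooplankton Communities
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for trait-based analysis of zooplankton survey data:
    functional-group classification from body size and feeding habit,
    abundance, dominance and alpha-diversity indices, Levins' niche breadth
    and proportional-similarity niche overlap, variance-ratio tests of
    overall interspecific association, phi-coefficient co-occurrence
    analysis with network export, and a seeded generator of synthetic
    estuarine survey datasets with known community structure for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
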