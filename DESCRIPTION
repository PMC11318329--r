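Package: clamtox
Title: Multi-Biomarker Assessment of Contaminant Toxicity in Bivalves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for chronic-exposure ecotoxicology studies on
    bivalves: a weighted histopathological condition index with severity
    classification, digestive-tubule histomorphometry, comet-assay DNA-damage
    endpoints computed from one-dimensional intensity profiles, Kaplan-Meier
    product-limit survival estimation with a k-group log-rank test, and
    one-way ANOVA with Tukey HSD multiple comparisons, percent-change effect
    sizes and compact letter displays. Includes a calibrated synthetic-data
    generator that emulates a three-group water-borne exposure design so the
    whole analysis chain is exercisable and testable without laboratory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
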