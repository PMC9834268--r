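Package: dropscreen
Title: Analysis of Droplet-Microfluidic Tumoroid Drug and Immune Screens
Version: 0.1.0
Authors@R:
    person("Screen", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of anchored-droplet microfluidic tumoroid
    screens: geometric and volumetric modelling of a hexagonal anchor-array
    chip, combinatorial fluorescent barcode construction and decoding,
    brightfield anchor detection and spheroid segmentation, propidium-iodide
    cytotoxicity scoring against a local-background threshold, and aggregation
    into growth curves, dose-response summaries and two-way ANOVA. Includes a
    ground-truthed synthetic chip-image generator so every stage is testable
    without microscope data, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
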