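Package: mitothermics
Title: Mitochondrial Bioenergetics and Whole-Body Metabolic Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for chronic-stress metabolic phenotyping
    studies: extraction of respiration states (state 2, 3, 4o, 3u) from
    plate-format oxygen-consumption-rate traces with protein and
    citrate-synthase normalization; respiratory control ratio and the
    thermodynamic coupling degree q with optimal efficiency and Stucki
    set-point classification; indirect-calorimetry substrate oxidation
    (RER, carbohydrate and fat oxidation, energy expenditure) over
    circadian light/dark windows; volcano-style differential protein
    abundance, EASE-style modified Fisher enrichment and pathway z-score
    estimation statistics; mtDNA copy-number ratios from qPCR; plus a
    seeded synthetic-data generator emulating all four input kinds so the
    full pipeline is testable without animal data.
License: MIT + file LICENSE
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
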