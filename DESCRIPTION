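Package: fibroquant
Title: Automated Digital Quantification of Pulmonary Fibrosis in Stained
    Whole Lung Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tile-based morphometry of whole-slide images of lung sections
    stained with picrosirius red and alcian blue or immunostained for CD68.
    Classifies every pixel into stain classes, segments the analyzable
    section area with automatic exclusion of large airway and vessel lumina,
    maps per-microtile tissue density, and computes mean pulmonary tissue
    density, fibrosis score, and collagen, mucus and CD68 area fractions.
    Includes a synthetic stained-section generator with pixel-exact ground
    truth, validation statistics (group summaries, two-sample t tests,
    Spearman correlation with exact small-sample permutation p values, and
    two-way ANOVA intraclass correlation for inter-rater reliability), and a
    batch command-line pipeline with run manifests for reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    png,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
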