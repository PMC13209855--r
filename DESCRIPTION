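Package: capmetrics
Title: Characterization Metrics for Spray-Dried Microcapsule Powders
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Particle sizing of spray-dried microcapsules from SEM-style
    micrographs (databar crop, contrast normalization, watershed instance
    segmentation, border-particle exclusion, minimum-enclosing-circle
    diameters, scale-bar calibration, D10/D50/D90 descriptors), powder
    quality-control equations (moisture, solubility, encapsulation
    efficiency, bulk and tapped density, Carr's Index, Hausner Ratio),
    formulation mass balance and lipid-core analyte concentration,
    external-standard HPLC quantification with signal-to-noise detection
    limits, and one-way ANOVA with Tukey HSD compact-letter grouping.
    Includes a ground-truthed synthetic-data generator for micrographs,
    replicate bench assays and chromatographic peak areas.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    EBImage,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
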