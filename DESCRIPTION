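Package: hepatoquant
Title: Histomorphometry and Immunostain Quantification for Liver Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies brightfield liver histology: red-blood-cell area and
    lipid-droplet morphometry on H&E fields, and DAB percent-positive-area on
    immunohistochemistry fields via Ruifrok-Johnston color deconvolution, with
    one-way ANOVA and Tukey HSD group comparison. Includes a synthetic
    histology-field generator with exact pixel-level ground truth so every
    stage of the pipeline can be validated without slide material, plus a
    batch pipeline that goes from simulation to per-group statistics and
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    withr,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
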