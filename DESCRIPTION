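Package: sgquant
Title: Quantitative Imaging of Secretory-Granule Docking and Exocytosis in
    Dividing Neuroendocrine Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-analysis pipeline for secretory-granule (SG) partitioning
    and regulated exocytosis in dividing PC12 cells. Implements
    membrane-stain (WGA) cell segmentation with classification of
    cluster-outer versus cluster-internal borders, 3-pixel surface-mask
    densitometry of surface-exposed secretogranin II with
    unstimulated-control background subtraction and responder
    classification, the 500-nm cortical-shell granule localization
    statistic with a pooled two-sample t comparison, and single-particle
    tracking with directed-motion classification, velocity estimation and
    track-microtubule colocalization. Ships seeded synthetic-microscopy
    generators (fluorescence scenes, EM-style granule scenes, particle
    track sets) with exact ground truth so every stage is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
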