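Package: ivmorph
Title: Real-Time Morphometric Workflow for Zebrafish Oocyte In Vitro Maturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based quantification of zebrafish oocyte diameter for in
    vitro maturation (IVM) assays. Provides a gradient-voting circle Hough
    transform for detecting oocytes in bright-field-like microscope frames,
    multi-frame consistency and overlap filtering with a manual-correction
    quality-control metric, stage-micrometer pixel-size calibration,
    diameter-based staging of stage III-V follicles, per-oocyte diameter-change
    and germinal vesicle breakdown (GVBD) endpoints summarised at the culture
    dish level, and the associated dish-level statistical pipeline (normality
    and variance checks, t tests, one-way ANOVA with Fisher's LSD post hoc).
    Includes a synthetic scene generator with exact ground truth for
    end-to-end validation of the workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    car,
    emmeans,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
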