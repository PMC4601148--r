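Package: focikit
Title: Quantification of DNA Damage Repair Foci and Colocalization in
    Fluorescence Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify DNA double-strand-break repair foci (such as
    gamma-H2AX and 53BP1) in multichannel fluorescence microscopy images.
    Provides nucleus segmentation from a DNA counterstain, difference-of-
    Gaussians enhancement of punctate focal signals, per-nucleus focus
    counting and projected-area measurement with a 3-pixel noise floor,
    Pearson and Manders colocalization coefficients computed per nucleus,
    repair-kinetics summaries (percent of foci repaired relative to the
    post-treatment maximum), and Shapiro-Wilk-gated two-sample t statistics.
    A seeded synthetic-image generator with planted ground truth supports
    validation of the whole pipeline without real confocal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
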