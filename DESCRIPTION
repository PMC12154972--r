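Package: dermometry
Title: Morphometry of Dermal Collagen in Light and Electron Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies hyaluronic-acid-induced remodelling of the dermal
    extracellular matrix from calibrated microscopy images. Implements an
    amorphous-ECM pixel-fraction statistic for H&E-stained light-microscopy
    sections and five transmission-electron-microscopy measurements of
    collagen architecture (bundle thickness, bundle linearity index, fibril
    diameter, interfibrillar distance, D-band periodicity), together with
    the group-comparison statistics (mean +/- SEM summaries, exact and
    approximate Mann-Whitney U tests, two-sample t-tests) and a full
    comparison plan over condition, timepoint and dermis layer. A seeded
    synthetic-image generator produces calibrated histology and TEM-like
    images with exact ground truth so the whole pipeline is testable
    without real specimens.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    png,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
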