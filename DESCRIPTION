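Package: fluoquant
Title: Absolute Fluorescent-Protein Quantification from Plate-Reader Fluorescence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts relative fluorescence units (RFU) measured on intact
    bacterial cell suspensions into absolute fluorescent-protein
    concentrations (mg/L). Implements standard-based linear calibration,
    SDS-PAGE densitometry scaling by host-cell protein, background and
    autofluorescence assessment, saturation/dilution bookkeeping, and an
    FDA-style analytical validation battery (linearity, LOD/LOQ, spike
    recovery, intraday/interday precision) with threshold-based pass/fail
    reporting. A seeded synthetic generator emulates a 24-h batch E. coli
    cultivation with growth-coupled reporter expression, glucose depletion,
    post-depletion signal decay and noisy plate-reader, gel and CFU
    observations so that every stage is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
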