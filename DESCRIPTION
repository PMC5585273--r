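Package: glycosearch
Title: Intact Glycopeptide Identification with Three-Level FDR Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Search engine for intact N-glycopeptide identification from
    stepped-collision-energy HCD tandem mass spectra. Implements a coarse
    glycan open search based on Y-ion ladder matching, fine scoring of glycan
    and peptide fragment evidence, target-decoy false discovery rate control
    at the glycan, peptide and glycopeptide levels, learning-to-rank
    calibration of the score parameters, and two search-engine-independent
    FDR validation estimators based on 15N/13C metabolic labeling and on an
    entrapment database.  A synthetic spectrum and benchmark generator makes
    the whole pipeline testable without instrument data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    e1071,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
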