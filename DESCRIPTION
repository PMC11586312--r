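Package: taumetry
Title: Linking Cellular Tau Pathology to Tau-PET Signal
Version: 0.1.0
Authors@R:
    person("taumetry", "developers", email = "taumetry@example.org",
           role = c("aut", "cre"))
Description: A quantitative bridge between cellular tau pathology and in
    vivo tau-PET signal in 4R-tauopathies. Provides morphometric
    classification of AT8-stained objects into dense neuronal or
    oligodendroglial (NFT/CB) and astrocytic (TA/TF) channels,
    autoradiography binding-ratio quantification with the associated
    correlation and regression battery, Logan graphical analysis of
    dynamic PET with image-derived input functions, single-cell
    radiotracing arithmetic including the cell-count extrapolation that
    ties cellular radioactivity to the PET signal increment, and layered
    cortical-surface SUVR sampling around the gray/white-matter boundary.
    Seeded synthetic-data generators emulate every input with ground
    truth attached so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
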