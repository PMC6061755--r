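Package: botanicad
Title: Multi-Detector Characterization and Relative Quantitation of Botanical Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Characterizes complex botanical extracts from combined charged
    aerosol detector (CAD), UV and high-resolution mass spectrometry (HRMS)
    acquisitions. Every chromatographic constituent is quantitated as a
    percentage of the total CAD signal, identified by molecular-formula
    assignment with an isotope-fit score, and correlated across detectors to
    produce a constituent report suitable for threshold-of-toxicological-
    concern (TTC) safety assessment. Includes exact-mass chemistry primitives
    (isotope envelopes, adduct arithmetic, ring-and-double-bond equivalents),
    chromatographic baseline estimation and peak detection with USP shape
    metrics, centroid-MS feature detection and adduct grouping, and a fully
    specified synthetic-extract simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
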