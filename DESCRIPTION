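Package: spatialcontact
Title: Contact-Domain Detection and Spatial Integration for 4C-seq
    Radiation-Response Studies
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects chromosomal contact domains from 4C-seq read counts on a
    HindIII restriction-fragment grid using a running-window enrichment
    p-score, percentile thresholding with permutation-based empirical false
    discovery rate, and run-length domain calling.  Integrates the called
    domains with ionizing-radiation dose/time expression clusters
    (differential expression and k-means kinetic clustering over five
    irradiation conditions) and with gamma-H2AX ChIP IP/input repair signal.
    Includes a synthetic-data generator that emulates bait-anchored 4C
    contact structure, radiation-response expression kinetics and
    compartment-dependent repair dynamics, so the whole pipeline runs at
    desk scale, plus a command-line driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
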