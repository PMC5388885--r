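Package: barcodekit
Title: DNA Barcode Assembly and Reference-Database Completeness Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building full-length plant DNA barcodes (rbcL, matK)
    from amplicon sequencing reads and for simulating how an incomplete
    reference barcode database mis-states its own diagnostic power. Two
    assemblers are provided: extended unidirectional consensus assembly
    (per-colony quality filtering, base-by-base directional consensus from
    the primer termini, and reverse-complement merging with summed base
    calls) and sonication micro-assembly (quality masking, read doubling,
    primer-seeded iterative extension by upstream-window matching). A
    comprehensive/incomplete reference barcode (CRB/IRB) model samples
    partial databases, classifies barcodes as perceived, ambiguous or false
    species-unique, identifies simulated field specimens under exact and
    percent-identity threshold matching, scans for optimal similarity
    thresholds, and fits power-law and exponential decay curves to
    performance trajectories. Seeded synthetic generators for barcode
    databases and sequencer reads make every component testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
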