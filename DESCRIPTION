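Package: mirrorCode
Title: Detection of CARC and CRAC Cholesterol-Recognition Motifs in
    Transmembrane Domains
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scans membrane-protein sequences for the two vectorial
    cholesterol-recognition motifs CARC ((K/R)-X(1-5)-(F/Y/W)-X(1-5)-(L/V))
    and CRAC ((L/V)-X(1-5)-(Y/F)-X(1-5)-(K/R)) inside transmembrane
    segments, extends annotated segment boundaries to interfacial
    basic residues, assigns each motif to the outer or inner membrane
    leaflet from protein topology, and classifies transmembrane domains
    as dual-mirror (one motif per leaflet), CARC-only, CRAC-only or
    motif-free. Includes a synthetic-protein generator with planted
    motifs and shuffle-based null frequencies for validation, plus desk
    scale analysis utilities for Langmuir-monolayer peptide insertion
    (critical insertion pressure extrapolation, adsorption kinetics)
    and deuterium quadrupolar splittings under motional averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
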