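Package: radgut
Title: Genotype-by-Irradiation Association Scanning of Gut Permeability
    in Inbred Fly Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening inbred reference-panel (DGRP-style)
    genotype data for markers whose effect on radiation-induced
    intestinal permeability depends on irradiation dose. Implements
    per-marker ordinary-least-squares fits of a genotype-by-dose
    interaction model with minor-allele-frequency filtering,
    permutation-based empirical false-discovery-rate estimation and
    candidate shortlisting, a consensus-motif scanner for Musashi
    binding elements in 3'UTR sequences, Smurf-assay and survival
    statistics (Kaplan-Meier, log-rank, delta-delta-Ct fold changes),
    and a seeded synthetic-data generator with planted effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    survival,
    BiocGenerics,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
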