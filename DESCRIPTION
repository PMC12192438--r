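Package: gvshuttle
Title: Giant Virus Vertical Transport and Carbon Export Flux Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pipeline for spatiotemporal analysis of giant virus (NCLDV)
    populations in ocean metagenome time series. Computes robust Q2Q3
    (central two quartiles) per-contig coverage from per-base depth tables,
    curates NCLDV contig catalogs from marker-gene hits, aggregates
    depth/time abundance profiles, calls vertical transport of populations
    into abyssal sediment-trap samples, classifies summer export pulses,
    and identifies populations whose trap abundance correlates positively
    with particulate carbon export flux via gene-significance statistics
    with an optional co-abundance (eigengene) module gate. Includes a
    synthetic-data generator that emulates the depth-niche, trap-block and
    flux-pulse structure of station time-series metagenomes so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
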