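Package: repliZones
Title: Calling and Analysis of Early Replication Initiation Zones from
    Dual-Label Nucleoside-Analog Incorporation Sequencing
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls early replication initiation zones (ERIZs) from
    dual-label (EdU/BrdU) and hydroxyurea-stalled (EdU/HU)
    nucleoside-incorporation coverage. Implements the delta-EB
    seed-and-extend caller on 5-kb binned RPM tracks, a global-rate
    Poisson enrichment scan with fold-change filtering for EdU/HU
    hotspots, interval arithmetic on BED-style regions, replication
    timing classification, transcription-context statistics around
    non-transcribed regions, a shuffle-based log-odds epigenetic
    feature predictor with logistic regression, and dCas9
    transcription-barrier replication profiles. A synthetic-data
    generator emulating the signal structure of these assays provides a
    fully reproducible test substrate.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
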