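Package: nascentmetrics
Title: Genome-Wide Quantification of Transcriptional Pausing, Elongation,
    and Splicing from Tag Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing signal-responsive gene activation from
    sequencing tag libraries: depth normalization of uniquely mapped tags,
    half-fragment tag shifting, TSS-anchored density profiles, promoter and
    gene-body counting, RPKM, elongation efficiency from stranded nascent
    transcription (GRO-Seq) tag densities, splicing efficiency from
    intron/exon densities and from 5' splice-junction 3'-end depletion,
    promoter enrichment-over-background calls, kinetic classification of
    immediate/early and late induced genes, induced-gene calling from
    gene-body counts, CAGE-based TSS refinement, promoter GC discrimination,
    positional TATA-box scanning, and known-motif enrichment. Includes a
    seeded synthetic-data generator with a planted ground-truth ledger so
    every estimator is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
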