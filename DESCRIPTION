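Package: fltrx
Title: Full-Length Transcriptome Characterization Without a Reference Genome
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing sets of full-length transcripts from
    single-molecule (Iso-Seq style) sequencing of non-model organisms, where
    no reference genome is available: greedy redundancy collapse at high
    identity, reference-free alternative-splicing detection from the geometry
    of paired local-alignment segments, microsatellite (SSR) scanning with
    MISA-style thresholds, open-reading-frame discovery with completeness
    classification, consensus long non-coding RNA filtering, KEGG-ortholog
    cataloguing of anthraquinone biosynthesis pathway genes, relative
    expression analysis by the 2^-ddCt method, and aggregate summary
    reporting.  A synthetic-transcriptome generator with a ground-truth
    manifest supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
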