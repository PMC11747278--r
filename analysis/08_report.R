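#!/usr/bin/env Rscript
# Stage 8: assemble the summary report.  Stage outputs computed here are
# merged with the study's printed external counts (read processing and
# BUSCO classes are upstream tools' outputs: consumed, never computed).

library(fltrx)

set <- read_fasta("results/synthetic/transcripts.fasta")
col <- collapse(set, threshold = 0.99)
hsps <- align_all_vs_all(set)
events <- detect_as_events(hsps, transcript_lengths(set))
loci <- scan_ssrs(set)
orfs <- find_orfs_set(set)
lnc <- consensus_lncrna(set)

rep <- build_report(
  stage_outputs = list(
    collapse = col,
    as_summary = summarize_as(events, col$clusters),
    ssr_stats = classify_ssr_types(loci),
    orfs = orfs,
    lncrna = lnc),
  external_counts = list(busco_single = 143L, busco_duplicated = 111L,
                         busco_fragmented = 18L, busco_missing = 31L))
jsonlite::write_json(list(counts = as.list(rep$counts),
                          percentages = as.list(rep$percentages)),
                     "results/report.json", auto_unbox = TRUE, digits = NA,
                     pretty = TRUE)
writeLines(render_report(rep), "results/report.txt")
print(rep)
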