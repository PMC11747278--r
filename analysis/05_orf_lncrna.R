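#!/usr/bin/env Rscript
# Stage 5: ORF discovery (both strands, >= 100 aa, first-ATG rule per
# stop-to-stop interval) and consensus lncRNA filtering (length > 200 nt
# plus the intersection of the longest-ORF and Fickett TESTCODE scorers).

library(fltrx)

set <- read_fasta("results/synthetic/transcripts.fasta")
man <- read_manifest("results/synthetic/manifest.json")

orfs <- find_orfs_set(set)
write_tsv_table(orfs[, setdiff(names(orfs), "protein")], "results/orfs.tsv")
complete <- orfs[orfs$completeness == "complete", ]
okey <- function(d) paste(d$transcript_id, d$start, d$end)
cat(sprintf("%d ORFs (%d complete); recovered %d/%d planted exactly\n",
            nrow(orfs), nrow(complete),
            sum(okey(man$planted_orfs) %in% okey(complete)),
            nrow(man$planted_orfs)))
hist <- orf_length_histogram(orfs)
jsonlite::write_json(as.list(hist), "results/orf_length_histogram.json",
                     auto_unbox = TRUE, pretty = TRUE)

lnc <- consensus_lncrna(set)
write_tsv_table(lnc$calls, "results/lncrna_calls.tsv")
jsonlite::write_json(lnc$venn, "results/lncrna_venn.json",
                     auto_unbox = TRUE, pretty = TRUE)
nc <- man$noncoding_ids
hit <- sum(lnc$calls$consensus_lncrna[match(nc, lnc$calls$transcript_id)])
cat(sprintf("consensus lncRNAs: %d of %d candidates; %d/%d planted noncoding called\n",
            lnc$venn$intersection, lnc$venn$n_candidates, hit, length(nc)))
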