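#!/usr/bin/env Rscript
# Stage 7: relative expression by 2^-ddCt on the packaged synthetic Ct
# fixture (the study's raw Ct values are not published, so this stage
# demonstrates the analysis contract on constructed data): underground vs
# aboveground, equal-variance t-test at the 1% level.

library(fltrx)

ct <- read_qpcr_table(system.file("extdata", "qpcr_ct_synthetic.tsv",
                                  package = "fltrx"))
res <- qpcr_analysis(ct, treatment_group = "underground",
                     control_group = "aboveground", alpha = 0.01)
write_tsv_table(res, "results/qpcr_fold_changes.tsv")
print(res, digits = 4)
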