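#!/usr/bin/env Rscript
# Stage 2: paired differential expression on both assays.
#
# Moderated t with empirical-Bayes variance shrinkage; features are called
# DE at |logFC| > 0.585 (1.5-fold) and BH FDR < 0.05.

library(synmir)

dat <- "results/data"
mirna <- read_expression(file.path(dat, "mirna_expression.tsv"),
                         file.path(dat, "mirna_design.tsv"))
mrna <- read_expression(file.path(dat, "mrna_expression.tsv"),
                        file.path(dat, "mrna_design.tsv"))

de_mirna <- paired_de(mirna)
de_mrna <- paired_de(mrna)
write.table(de_mirna, "results/de_mirna.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(de_mrna, "results/de_mrna.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- readLines(file.path(dat, "truth_de_mirnas.txt"))
found <- de_features(de_mirna)
message(sum(de_mirna$is_de), " DE miRNAs, ", sum(de_mrna$is_de),
        " DE genes")
message("planted miRNA recall: ", round(mean(truth %in% found), 2))
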