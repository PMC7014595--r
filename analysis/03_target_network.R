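#!/usr/bin/env Rscript
# Stage 3: bipartite miRNA-target network.
#
# Pearson correlation of each DE miRNA against each DE gene over all 34
# pooled samples; edges kept at r <= -0.6 together with a prediction row
# at PCT > 0.5, carrying the context+ score w.

library(synmir)

dat <- "results/data"
mirna <- read_expression(file.path(dat, "mirna_expression.tsv"),
                         file.path(dat, "mirna_design.tsv"))
mrna <- read_expression(file.path(dat, "mrna_expression.tsv"),
                        file.path(dat, "mrna_design.tsv"))
pred <- read_predictions(file.path(dat, "predictions.tsv"))
de_m <- de_features(read.table("results/de_mirna.tsv", header = TRUE,
                               sep = "\t"))
de_g <- de_features(read.table("results/de_mrna.tsv", header = TRUE,
                               sep = "\t"))

cors <- correlate_pairs(mirna, mrna, de_m, de_g)
net <- build_target_network(cors, pred)
write_edge_list(net, "results/target_network.tsv")
write_graphml(net, "results/target_network.graphml")

print(net)
truth <- read.table(file.path(dat, "truth_edges.tsv"), header = TRUE,
                    sep = "\t")
tk <- paste(truth$mirna_id, truth$gene_id)
nk <- paste(net$edges$mirna_id, net$edges$gene_id)
message("planted edge recall: ", round(mean(tk %in% nk), 2),
        ";  false-edge rate: ", round(mean(!(nk %in% tk)), 2))
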