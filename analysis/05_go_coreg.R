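#!/usr/bin/env Rscript
# Stage 5: functional co-regulation.
#
# Each network miRNA's target set is tested for GO-term over-representation
# (hypergeometric, BH < 0.05); for every miRNA pair the number N of terms
# significant in both is counted and the pair classed low (N <= 10) or
# high (N > 10). A random-group control samples equally sized miRNA groups
# from the full prediction background and records the null high fraction
# over all pairs including self-pairs.

library(synmir)

dat <- "results/data"
mrna <- read_expression(file.path(dat, "mrna_expression.tsv"),
                        file.path(dat, "mrna_design.tsv"))
anno <- read_gmt(file.path(dat, "annotation.gmt"))
pred <- read_predictions(file.path(dat, "predictions.tsv"))
net_edges <- read.table("results/target_network.tsv", header = TRUE,
                        sep = "\t")

target_sets <- split(as.character(net_edges$node2),
                     as.character(net_edges$node1))
universe <- intersect(rownames(mrna$values), unique(unlist(anno)))

coreg <- coregulation_counts(target_sets, anno, universe)
write.table(coreg, "results/coregulation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(nrow(coreg), " miRNA pairs; high co-regulation (N > 10): ",
        sum(coreg$group == "high"))

# control: random groups of the same size drawn from all miRNAs with >= 3
# high-PCT predicted targets
bg <- split(pred$gene_id[pred$pct > 0.5], pred$mirna_id[pred$pct > 0.5])
bg <- bg[lengths(bg) >= 3]
for (m in names(target_sets)) bg[[m]] <- target_sets[[m]]
gs <- length(target_sets)
ctl <- random_group_control(bg, group_size = gs, n_reps = 100,
                            annotation = anno, universe = universe,
                            seed = 20240905,
                            observed_mirnas = names(target_sets))
message("observed high fraction (", pair_count(gs), " pairs incl. self): ",
        round(ctl$observed_high_fraction, 3))
message("random-group mean high fraction: ",
        round(mean(ctl$null_high_fractions), 3),
        "  (empirical p = ", signif(ctl$p_value, 3), ")")
ctl_tab <- data.frame(replicate = seq_along(ctl$null_high_fractions),
                      null_high_fraction = ctl$null_high_fractions)
write.table(ctl_tab, "results/coreg_control.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
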