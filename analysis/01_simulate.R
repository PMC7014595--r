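#!/usr/bin/env Rscript
# Stage 1: generate the synthetic matched tumor/normal study.
#
# 17 matched pairs, 50 miRNAs, 1000 genes; 10 DE miRNAs (down-regulated in
# tumors by 1 log2 unit on average), 150 DE genes; one planted synergistic
# miRNA pair sharing 20 targets with weight-profile correlation 0.95.
# Everything downstream reads only the files written here.

library(synmir)

out <- "results/data"
cfg <- sim_config(seed = 20240901)
sim <- simulate_dataset(cfg)
write_simulation(sim, out)

message("wrote ", length(list.files(out)), " files to ", out)
message("planted DE miRNAs: ", paste(sim$truth$de_mirnas, collapse = ", "))
pt <- sim$truth$pairs[[1]]
message("planted synergistic pair: ", pt$mirna_a, " + ", pt$mirna_b,
        " (", pt$n_shared, " shared targets, profile r = ",
        pt$profile_cor, ")")
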