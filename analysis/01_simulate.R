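#!/usr/bin/env Rscript
# Generate the synthetic ABA time-course dataset used by the downstream
# analysis steps: 2,000 genes, treated/control x 30/60/180 min x 3 replicates,
# with planted temporal response archetypes and gene-specific noise.
# Writes: results/sim/matrix.tsv, samples.tsv, truth.tsv

library(abatime)

dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)
cfg <- sim_config(n_genes = 2000, seed = 20260924)
sim <- generate_timecourse(cfg)

write_expression(sim$matrix, "results/sim/matrix.tsv", "results/sim/samples.tsv")
write.table(sim$truth, "results/sim/truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("simulated", nrow(sim$truth), "genes;", "archetype counts:\n")
print(table(sim$truth$archetype))
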