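#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study: a 99-species Yule phylogeny,
# replicate-level chemical peak tables for males, virgin females and
# mated females (~250 features per sex, 43/9 sex-specific, six
# replicates per stratum), and the single-sensillum response panel, all
# with known ground truth. Downstream stages read these files only.

suppressPackageStartupMessages(library(chemophylo))

out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20260923L)
sim <- simulate_peak_table(cfg)
rsim <- simulate_response_matrix(sim$truth, cfg)

write_newick(sim$tree, file.path(out, "tree.nwk"))
write.table(sim$peak_table, file.path(out, "peak_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rsim$response_matrix, file.path(out, "response_matrix.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$compounds, file.path(out, "truth_compounds.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$producing, file.path(out, "truth_producing.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rsim$truth_edges, file.path(out, "truth_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d species, %d peak records, %d response cells\n",
            cfg$n_species, nrow(sim$peak_table),
            nrow(rsim$response_matrix)))
cat(sprintf("ground truth: %d male-specific, %d female-specific, %d transferred\n",
            sum(sim$truth$compounds$specificity == "male_specific"),
            sum(sim$truth$compounds$specificity == "female_specific"),
            sum(sim$truth$compounds$transferred, na.rm = TRUE)))
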