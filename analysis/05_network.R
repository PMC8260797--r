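#!/usr/bin/env Rscript
# Stage 5 — the olfactory communication network: detection edges above
# the 10 spikes/s exclusion threshold, per-species clustering
# coefficients through at1 and at4, the at1-vs-at4 Mann-Whitney
# comparison, and the self-loop (conspecific detection) summary.

suppressPackageStartupMessages(library(chemophylo))

ind <- "results/simulated"
out <- "results/network"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pt <- read_peak_table(file.path(ind, "peak_table.tsv"))
rm <- read_response_matrix(file.path(ind, "response_matrix.tsv"))
catalog <- call_sex_specific(pt)

net <- build_network(catalog, rm, threshold = 10)
print(net)
write_network(net, file.path(out, "edges.tsv"))

cc <- clustering_coefficients(net)
write.table(cc, file.path(out, "clustering_coefficients.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("mean clustering coefficient: at1 %.3f, at4 %.3f\n",
            mean(cc$at1), mean(cc$at4)))

cmp <- compare_coefficients(net)
print(cmp)

loops <- self_loop_summary(net)
write.table(loops$table, file.path(out, "self_loops.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("self-loops: at1 %d, at4 %d of %d species\n",
            loops$totals[["at1"]], loops$totals[["at4"]],
            length(net$nodes)))

# recovery against the planted network
truth <- read.delim(file.path(ind, "truth_edges.tsv"))
key <- function(d) paste(d$detector, d$producer, d$sensillum)
got <- key(net$edges); want <- key(truth)
cat(sprintf("edge recovery: %d/%d planted edges found, %d spurious\n",
            length(intersect(got, want)), length(want),
            length(setdiff(got, want))))
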