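#!/usr/bin/env Rscript
# Step 2 — interaction networks and emergent indices.
#
# For every host and each of the four interaction types (mutualism,
# antagonism, aggression, altruism): log10-transform abundances, evaluate the
# pairwise descriptor, min-max normalize, threshold (0.95; altruism 0.99) and
# summarize the resulting network by six indices. Also builds the consensus
# network per type, compares bacterial vs fungal degree, and tabulates
# interkingdom edges by class.

suppressPackageStartupMessages(library(micronetgwas))

taxonomy <- read_taxonomy("results/data/taxonomy.tsv")
abundance <- read_otu_table("results/data/otu_table.tsv", taxonomy, top_k = 100)

indices <- index_table(abundance, taxonomy)
dir.create("results", showWarnings = FALSE)
write.table(indices, "results/index_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("index table: %d hosts x %d phenotypes",
                nrow(indices), ncol(indices) - 1))

for (ty in c("mutualism", "antagonism", "aggression", "altruism")) {
  net <- consensus_network(abundance, taxonomy, ty)
  write_network(net, sprintf("results/network_%s.graphml", ty), "graphml")
  write_network(net, sprintf("results/network_%s_edges.tsv", ty), "edgelist-tsv")
  kt <- kingdom_degree_test(net)
  ik <- interkingdom_edges(net)
  write.table(ik$interkingdom, sprintf("results/interkingdom_%s.tsv", ty),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf(
    "%-10s consensus: %4d edges | bacteria vs fungi degree: W = %.0f, P = %.3g (medians %.0f/%.0f) | interkingdom edges: %d",
    ty, igraph::ecount(net), kt$statistic, kt$p_value,
    kt$medians[["bacteria"]], kt$medians[["fungi"]],
    sum(ik$interkingdom$n_edges)))
}
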