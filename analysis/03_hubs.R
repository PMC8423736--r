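#!/usr/bin/env Rscript
# Step 3 — hub taxa.
#
# Calls hubs on each consensus network as the nodes strictly exceeding the
# 0.90 quantile of both degree and closeness (computed on the symmetrized
# topology), compares hub vs non-hub abundance, and reports hubs shared
# across the four network types.

suppressPackageStartupMessages(library(micronetgwas))

taxonomy <- read_taxonomy("results/data/taxonomy.tsv")
abundance <- read_otu_table("results/data/otu_table.tsv", taxonomy, top_k = 100)

reports <- list()
for (ty in c("mutualism", "antagonism", "aggression", "altruism")) {
  net <- consensus_network(abundance, taxonomy, ty)
  rep_ty <- detect_hubs(hub_centralities(net), type = ty, taxonomy = taxonomy)
  reports[[ty]] <- rep_ty
  print(rep_ty)
  write.table(rep_ty$hubs, sprintf("results/hubs_%s.tsv", ty),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(rep_ty$hubs) > 0 && nrow(rep_ty$hubs) < nrow(abundance)) {
    ab_test <- hub_abundance_test(rep_ty, abundance)
    message(sprintf(
      "  %s more abundant than %s? one-sided P = %.3g (means %.2f vs %.2f)",
      rep_ty$roles[["hub"]], rep_ty$roles[["other"]],
      ab_test$p_one_sided, ab_test$group_means[["hubs"]],
      ab_test$group_means[["others"]]))
  }
}

sh <- shared_hubs(reports, taxonomy)
write.table(sh$membership, "results/hub_membership.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("%d distinct hub OTUs across the four networks",
                nrow(sh$membership)))
message("pairwise shared-phylum counts:")
print(sh$phylum_overlap)
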