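#!/usr/bin/env Rscript
# Step 5 — epistatic QTL networks.
#
# For each phenotype with >= 2 significant SNPs: genotype-mean transform the
# phenotype, learn a directed acyclic network over the hit SNPs by BIC hill
# climbing, and call hub QTLs (total degree strictly above the 0.90 quantile
# among non-isolated nodes). Edge orientations are statistical dependency
# orientations, not biological causality claims.

suppressPackageStartupMessages(library(micronetgwas))

seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
taxonomy <- read_taxonomy("results/data/taxonomy.tsv")
abundance <- read_otu_table("results/data/otu_table.tsv", taxonomy, top_k = 100)
G <- read_genotypes("results/data/genotypes.tsv", abundance)
indices <- read.delim("results/index_table.tsv", check.names = FALSE)
hits <- read.delim("results/gwas_hits.tsv")

Gf <- maf_filter(G[indices$host_id, , drop = FALSE])
hub_rows <- NULL
for (ph in unique(hits$phenotype)) {
  snps <- hits$snp[hits$phenotype == ph]
  if (length(snps) < 2) next
  y <- log_phenotype(indices[[ph]])
  gm <- genotype_mean_transform(y, Gf[, snps, drop = FALSE])
  net <- learn_bn(gm, seed = seed)
  write.table(net$edges, sprintf("results/qtl_network_%s_edges.tsv", ph),
              sep = "\t", quote = FALSE, row.names = FALSE)
  hq <- hub_qtls(net)
  message(sprintf("%-28s %d SNPs, %d edges, %d hub QTLs (BIC %.1f)",
                  ph, length(net$nodes), nrow(net$edges), length(hq),
                  net$score))
  if (length(hq) > 0) {
    hub_rows <- rbind(hub_rows, data.frame(phenotype = ph, snp = hq))
  }
}
if (is.null(hub_rows)) hub_rows <- data.frame(phenotype = character(0),
                                              snp = character(0))
write.table(hub_rows, "results/hub_qtls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("%d hub QTL calls in total", nrow(hub_rows)))
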