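#!/usr/bin/env Rscript
# Step 4 — association mapping of the network indices.
#
# Each of the 24 index phenotypes is log-transformed and scanned against all
# SNPs with MAF > 5% by single-marker OLS; hits are SNPs at
# -log10(P) >= 5. Genomic-control lambda and SNP heritability (single-SNP
# and joint R2 of the hits) are reported per phenotype, and hit recovery is
# checked against the planted ground truth.

suppressPackageStartupMessages(library(micronetgwas))

taxonomy <- read_taxonomy("results/data/taxonomy.tsv")
abundance <- read_otu_table("results/data/otu_table.tsv", taxonomy, top_k = 100)
G <- read_genotypes("results/data/genotypes.tsv", abundance)
indices <- read.delim("results/index_table.tsv", check.names = FALSE)
truth <- read.delim("results/data/ground_truth.tsv")

scan <- gwas_scan(indices, G)

all_res <- do.call(rbind, lapply(names(scan), function(ph) {
  cbind(phenotype = ph, scan[[ph]]$result)
}))
write.table(all_res, "results/gwas_results.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
hits <- do.call(rbind, lapply(names(scan), function(ph) {
  h <- scan[[ph]]$hits
  if (nrow(h) == 0) NULL else cbind(phenotype = ph, h)
}))
if (is.null(hits)) hits <- data.frame(phenotype = character(0), snp = character(0))
write.table(hits, "results/gwas_hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

summary_tab <- data.frame(
  phenotype = names(scan),
  lambda_gc = sapply(scan, function(s) s$lambda),
  n_hits = sapply(scan, function(s) nrow(s$hits)),
  total_h2 = sapply(scan, function(s) s$heritability$total)
)
write.table(summary_tab, "results/heritability.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("%d hit rows across %d phenotypes; %d distinct significant SNPs",
                nrow(hits), length(scan), length(unique(hits$snp))))
per_type <- table(sub("_.*", "", hits$phenotype))
for (ty in names(per_type)) {
  message(sprintf("  acting through %-10s: %d (%.1f%%)", ty, per_type[[ty]],
                  100 * per_type[[ty]] / nrow(hits)))
}
message(sprintf("lambda_GC range across phenotypes: [%.3f, %.3f]",
                min(summary_tab$lambda_gc), max(summary_tab$lambda_gc)))
message(sprintf("total SNP-h2 range: [%.3f, %.3f]",
                min(summary_tab$total_h2), max(summary_tab$total_h2)))
recovered <- intersect(unique(hits$snp), unique(truth$snp_id))
message(sprintf("planted causal SNPs recovered among hits: %d of %d",
                length(recovered), length(unique(truth$snp_id))))
message("(abundance-mode effects reach the indices attenuated by the nonlinear")
message(" descriptor->threshold->index map; see the index-mode check below)")

# index-mode check: an effect planted directly on an index phenotype,
# sized to explain ~15% of its variance, should top the ranking
seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
set.seed(seed)
sds <- vapply(setdiff(names(indices), "host_id"),
              function(cl) sd(indices[[cl]]), numeric(1))
target <- names(which.max(sds))
Gm <- maf_filter(G[indices$host_id, , drop = FALSE])
causal <- sample(colnames(Gm), 1)
x <- Gm[, causal]
y0 <- log_phenotype(indices[[target]])
beta <- sqrt(0.15 / 0.85 * var(y0) / var(x))
res_im <- associate(y0 + beta * x, Gm)
rank_causal <- match(causal, res_im$snp[order(res_im$p_value)])
message(sprintf(
  "index mode: effect on %s via %s -> causal SNP ranked %d of %d (P = %.2e)",
  target, causal, rank_causal, nrow(res_im),
  res_im$p_value[res_im$snp == causal]))
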