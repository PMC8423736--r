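#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study.
#
# 179 host accessions, a panel of 100 bacterial + 100 fungal OTUs, 2000
# biallelic SNPs spanning both sides of the 5% MAF filter, and 25 causal SNPs
# each shifting the log10 abundance of 3 OTUs by 0.6 per minor allele.
# Writes the OTU table, taxonomy, genotypes (TSV + VCF) and the planted
# ground truth under results/data/.

suppressPackageStartupMessages(library(micronetgwas))

seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
cfg <- simulation_config(n_hosts = 179, n_bacteria = 100, n_fungi = 100,
                         n_snps = 2000, n_causal = 25, effect_size = 0.6,
                         n_affected_otus = 3, seed = seed)
sim <- simulate_dataset(cfg)
paths <- write_dataset(sim, "results/data")

message(sprintf("hosts: %d   OTUs: %d (%d bacteria / %d fungi)   SNPs: %d",
                ncol(sim$abundance), nrow(sim$abundance),
                sum(sim$taxonomy$kingdom == "bacteria"),
                sum(sim$taxonomy$kingdom == "fungi"), ncol(sim$genotypes)))
message(sprintf("planted: %d causal SNPs -> %d (SNP, OTU) effects of %.2f on log10 abundance",
                length(unique(sim$truth$snp_id)), nrow(sim$truth),
                cfg$effect_size))
message("written: ", paste(basename(paths), collapse = ", "))
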