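#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study design the pipeline targets: 179 inbred host accessions, a panel of
#' the 100 most abundant bacterial plus 100 most abundant fungal OTUs, and a
#' dense biallelic SNP matrix spanning allele frequencies on both sides of the
#' 5% MAF filter.
#'
#' @param n_hosts Number of host accessions (inbred, homozygous).
#' @param n_bacteria,n_fungi OTUs per kingdom.
#' @param n_snps Number of biallelic SNPs.
#' @param maf_range Interval within (0, 0.5] from which each SNP's minor
#'   allele frequency is drawn uniformly.
#' @param n_causal Number of causal SNPs planted on abundances.
#' @param effect_size Per-allele shift on log10 abundance for each planted
#'   (SNP, OTU) pair.
#' @param n_affected_otus OTUs affected by each causal SNP.
#' @param abundance_log_mean_range Range of per-OTU baseline log10 abundance.
#' @param abundance_log_sd Gaussian noise sd on log10 abundance (> 0).
#' @param n_subpops Number of subpopulations (1 = no structure).
#' @param divergence Balding-Nichols-style divergence constant F in (0, 1)
#'   controlling between-subpopulation allele-frequency spread.
#' @param seed Integer seed; every simulate_* op derives its stream from it.
#' @return A list of class \code{"sim_config"}.
#' @export
simulation_config <- function(n_hosts = 179L,
                              n_bacteria = 100L,
                              n_fungi = 100L,
                              n_snps = 1000L,
                              maf_range = c(0.02, 0.5),
                              n_causal = 0L,
                              effect_size = 0,
                              n_affected_otus = 1L,
                              abundance_log_mean_range = c(1, 4),
                              abundance_log_sd = 0.5,
                              n_subpops = 1L,
                              divergence = 0.1,
                              seed = 1L) {
  cfg <- list(
    n_hosts = as.integer(n_hosts), n_bacteria = as.integer(n_bacteria),
    n_fungi = as.integer(n_fungi), n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range), n_causal = as.integer(n_causal),
    effect_size = as.numeric(effect_size),
    n_affected_otus = as.integer(n_affected_otus),
    abundance_log_mean_range = as.numeric(abundance_log_mean_range),
    abundance_log_sd = as.numeric(abundance_log_sd),
    n_subpops = as.integer(n_subpops), divergence = as.numeric(divergence),
    seed = as.integer(seed)
  )
  if (cfg$n_hosts < 2) stop("invalid configuration: n_hosts < 2")
  if (cfg$n_snps < 1) stop("invalid configuration: n_snps = 0")
  if (cfg$n_causal > cfg$n_snps) stop("invalid configuration: n_causal > n_snps")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("invalid configuration: maf_range must lie within (0, 0.5]")
  }
  if (cfg$abundance_log_sd <= 0) stop("invalid configuration: abundance_log_sd <= 0")
  if (cfg$n_bacteria + cfg$n_fungi < 2) stop("invalid configuration: need >= 2 OTUs")
  class(cfg) <- "sim_config"
  cfg
}

# per-op deterministic substreams derived from the config seed
.op_seed <- function(config, offset) {
  (config$seed + offset) %% .Machine$integer.max
}

#' Simulate inbred-host genotypes
#'
#' Draws each SNP's population minor-allele frequency uniformly from
#' \code{maf_range}; with \code{n_subpops > 1}, per-subpopulation frequencies
#' are perturbed Balding-Nichols style, i.e. drawn from
#' \code{Beta(p(1-F)/F, (1-p)(1-F)/F)} with divergence constant \code{F}.
#' Hosts are assigned to subpopulations in blocks. Calls are 0 (major) / 1
#' (minor), one allele per host (homozygous inbred coding).
#'
#' @param config A [simulation_config()].
#' @return Integer matrix hosts x SNPs with dimnames \code{host_*}/\code{snp_*}
#'   and attributes \code{maf} (population frequencies) and \code{subpop}
#'   (host assignments).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.op_seed(config, 0L))
  n <- config$n_hosts
  s <- config$n_snps
  p <- stats::runif(s, config$maf_range[1], config$maf_range[2])
  subpop <- rep(seq_len(config$n_subpops), length.out = n)
  subpop <- sort(subpop)
  G <- matrix(0L, n, s,
              dimnames = list(paste0("host_", seq_len(n)),
                              paste0("snp_", seq_len(s))))
  if (config$n_subpops > 1) {
    f <- config$divergence
    for (k in seq_len(config$n_subpops)) {
      pk <- stats::rbeta(s, p * (1 - f) / f, (1 - p) * (1 - f) / f)
      idx <- which(subpop == k)
      G[idx, ] <- matrix(stats::rbinom(length(idx) * s, 1L, rep(pk, each = length(idx))),
                         length(idx), s)
    }
  } else {
    G[, ] <- matrix(stats::rbinom(n * s, 1L, rep(p, each = n)), n, s)
  }
  attr(G, "maf") <- p
  attr(G, "subpop") <- subpop
  G
}

#' Simulate an OTU taxonomy table
#'
#' OTUs 1..n_bacteria are bacteria, the next n_fungi are fungi; phylum and
#' class labels cycle through a small fixed vocabulary typical of root
#' microbiomes.
#'
#' @param config A [simulation_config()].
#' @return data.frame with columns \code{otu_id}, \code{kingdom},
#'   \code{phylum}, \code{class}.
#' @export
simulate_taxonomy <- function(config) {
  bact_phyla <- c("Proteobacteria", "Actinobacteria", "Bacteroidetes", "Chloroflexi")
  bact_class <- c("Betaproteobacteria", "Actinobacteria", "Flavobacteriia",
                  "Gammaproteobacteria", "Alphaproteobacteria", "Sphingobacteriia")
  fung_phyla <- c("Ascomycota", "Basidiomycota", "Mortierellomycota")
  fung_class <- c("Leotiomycetes", "Dothideomycetes", "Sordariomycetes",
                  "Agaricomycetes", "Mortierellomycetes")
  nb <- config$n_bacteria
  nf <- config$n_fungi
  ids <- seq_len(nb + nf)
  data.frame(
    otu_id = paste0("OTU_", ids),
    kingdom = rep(c("bacteria", "fungi"), c(nb, nf)),
    phylum = c(rep_len(bact_phyla, nb), rep_len(fung_phyla, nf))[seq_len(nb + nf)],
    class = c(rep_len(bact_class, nb), rep_len(fung_class, nf))[seq_len(nb + nf)],
    stringsAsFactors = FALSE
  )
}

#' Simulate host x OTU abundances with planted SNP effects
#'
#' Per-OTU baseline log10 abundances are drawn uniformly from
#' \code{abundance_log_mean_range} and sorted decreasing within kingdom, so
#' lower OTU ids are the more abundant taxa (mirroring a "most abundant"
#' selection). The log10 abundance of OTU j in host i is
#' \code{baseline_j + sum over causal SNPs s affecting j of effect * x_is +
#' N(0, abundance_log_sd)}, returned on the raw scale \code{10^log10}.
#'
#' @param genotypes Matrix from [simulate_genotypes()].
#' @param taxonomy Table from [simulate_taxonomy()].
#' @param config A [simulation_config()]; \code{n_causal} SNPs are sampled
#'   from the genotype panel and each assigned \code{n_affected_otus} target
#'   OTUs.
#' @return List with \code{abundance} (OTUs x hosts matrix, strictly positive)
#'   and \code{truth} (data.frame snp_id, otu_id, effect).
#' @export
simulate_abundances <- function(genotypes, taxonomy, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(genotypes) != config$n_hosts) {
    stop("dimension error: genotype hosts do not match config")
  }
  set.seed(.op_seed(config, 1L))
  n <- config$n_hosts
  m <- nrow(taxonomy)
  base <- stats::runif(m, config$abundance_log_mean_range[1],
                       config$abundance_log_mean_range[2])
  for (kd in unique(taxonomy$kingdom)) {
    idx <- which(taxonomy$kingdom == kd)
    base[idx] <- sort(base[idx], decreasing = TRUE)
  }
  logab <- matrix(base, m, n) +
    matrix(stats::rnorm(m * n, 0, config$abundance_log_sd), m, n)
  truth <- data.frame(snp_id = character(0), otu_id = character(0),
                      effect = numeric(0), stringsAsFactors = FALSE)
  if (config$n_causal > 0) {
    causal <- sample(colnames(genotypes), config$n_causal)
    for (s in causal) {
      otus <- sample(seq_len(m), min(config$n_affected_otus, m))
      for (j in otus) {
        logab[j, ] <- logab[j, ] + config$effect_size * genotypes[, s]
        truth <- rbind(truth, data.frame(
          snp_id = s, otu_id = taxonomy$otu_id[j],
          effect = config$effect_size, stringsAsFactors = FALSE))
      }
    }
  }
  ab <- 10^logab
  dimnames(ab) <- list(taxonomy$otu_id, rownames(genotypes))
  list(abundance = ab, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Composes [simulate_genotypes()], [simulate_taxonomy()] and
#' [simulate_abundances()] into one reproducible dataset.
#'
#' @param config A [simulation_config()].
#' @return List with \code{genotypes}, \code{taxonomy}, \code{abundance},
#'   \code{truth} and the \code{config}.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  g <- simulate_genotypes(config)
  tx <- simulate_taxonomy(config)
  ab <- simulate_abundances(g, tx, config)
  list(genotypes = g, taxonomy = tx, abundance = ab$abundance,
       truth = ab$truth, config = config)
}

#' Plant an effect directly on an emergent index ("index mode")
#'
#' The abundance->network->index map is nonlinear, so effects planted on
#' abundances reach the phenotype attenuated. For clean power and calibration
#' studies this helper adds \code{effect * genotype} directly to one column of
#' an index table after computation, isolating the association-mapping stage.
#'
#' @param index_table data.frame from [index_table()] (or any host-rowed
#'   phenotype table).
#' @param genotypes Genotype matrix aligned to the table's hosts.
#' @param snp_id Column of \code{genotypes} to use.
#' @param column Index column to shift.
#' @param effect Per-allele additive shift.
#' @return The table with the shifted column; attribute \code{truth} records
#'   the planted (snp, column, effect).
#' @export
plant_index_effect <- function(index_table, genotypes, snp_id, column, effect) {
  stopifnot(column %in% names(index_table), snp_id %in% colnames(genotypes))
  x <- genotypes[index_table$host_id, snp_id]
  index_table[[column]] <- index_table[[column]] + effect * x
  attr(index_table, "truth") <- data.frame(
    snp_id = snp_id, column = column, effect = effect, stringsAsFactors = FALSE)
  index_table
}

#' Write a simulated dataset to a directory
#'
#' Emits the OTU table, taxonomy and genotypes (TSV and VCF) plus the planted
#' ground truth, in the formats the readers in this package parse back.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of paths written.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    otu = file.path(dir, "otu_table.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    genotypes_tsv = file.path(dir, "genotypes.tsv"),
    genotypes_vcf = file.path(dir, "genotypes.vcf"),
    truth = file.path(dir, "ground_truth.tsv")
  )
  write_otu_table(sim$abundance, paths["otu"])
  write_tsv(sim$taxonomy, paths["taxonomy"])
  write_genotypes_tsv(sim$genotypes, paths["genotypes_tsv"])
  write_genotypes_vcf(sim$genotypes, paths["genotypes_vcf"])
  write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}
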