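# One-call orchestration: io -> descriptors -> networks -> hubs -> gwas ->
# qtl networks, with a JSON manifest recording every parameter and
# convention so a run is reproducible from the manifest alone.

#' Assemble a pipeline run configuration
#'
#' Defaults are the analysis' shipped settings: 100 OTUs per kingdom,
#' retention thresholds 0.95/0.95/0.95/0.99, MAF > 5\%, significance line
#' -log10(p) >= 5.
#'
#' @param otu_table,taxonomy,genotypes Input file paths.
#' @param covariates Optional covariate TSV path (host_id + numeric columns).
#' @param top_k OTUs kept per kingdom.
#' @param tau Named thresholds per interaction type.
#' @param scope Normalization scope, "per-host" or "global".
#' @param hub_mode,hub_degree,hub_closeness Hub-calling mode and cutoffs.
#' @param maf MAF filter bound.
#' @param logp Significance line on -log10 scale.
#' @param max_parents,restarts Bayesian-network search parameters.
#' @param seed Integer seed.
#' @param out Output directory.
#' @return List of class \code{"run_config"}.
#' @export
run_config <- function(otu_table, taxonomy, genotypes, covariates = NULL,
                       top_k = 100,
                       tau = c(mutualism = 0.95, antagonism = 0.95,
                               aggression = 0.95, altruism = 0.99),
                       scope = "per-host",
                       hub_mode = "quantile", hub_degree = 0.90,
                       hub_closeness = 0.90,
                       maf = 0.05, logp = 5,
                       max_parents = 3, restarts = 10,
                       seed = 1, out = "results") {
  structure(list(
    otu_table = otu_table, taxonomy = taxonomy, genotypes = genotypes,
    covariates = covariates, top_k = top_k, tau = tau, scope = scope,
    hub_mode = hub_mode, hub_degree = hub_degree,
    hub_closeness = hub_closeness, maf = maf, logp = logp,
    max_parents = max_parents, restarts = restarts,
    seed = as.integer(seed), out = out
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Checks parameter ranges and input-file existence; returns a character
#' vector of violations (empty when the config is valid) rather than
#' erroring.
#'
#' @param config A [run_config()].
#' @return Character vector of violations; \code{character(0)} means ok.
#' @export
validate_config <- function(config) {
  v <- character(0)
  for (f in c("otu_table", "taxonomy", "genotypes")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      v <- c(v, sprintf("missing input file: %s", f))
    }
  }
  if (!is.null(config$covariates) && !file.exists(config$covariates)) {
    v <- c(v, "missing input file: covariates")
  }
  if (any(config$tau <= 0 | config$tau >= 1)) {
    v <- c(v, "tau must lie in (0, 1)")
  }
  if (config$maf <= 0 || config$maf >= 0.5) {
    v <- c(v, "maf must lie in (0, 0.5)")
  }
  if (config$logp <= 0) v <- c(v, "logp must be positive")
  if (config$top_k < 1) v <- c(v, "top_k must be >= 1")
  if (!config$scope %in% c("per-host", "global")) {
    v <- c(v, "scope must be per-host or global")
  }
  v
}

#' Run the full network-mapping pipeline
#'
#' Executes read -> descriptor networks -> emergent indices -> hub calling
#' (consensus networks) -> per-SNP association for all 24 phenotypes -> QTL
#' network learning over each phenotype's significant SNPs, writing all
#' artifacts plus a JSON manifest under \code{config$out}. Reruns with the
#' same inputs and seed are byte-identical.
#'
#' @param config A validated [run_config()].
#' @return Invisibly, a list with the main in-memory results (indices,
#'   hub reports, gwas scan, qtl networks, manifest).
#' @export
run_pipeline <- function(config) {
  viol <- validate_config(config)
  if (length(viol) > 0) {
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "))
  }
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  taxonomy <- stage("io", read_taxonomy(config$taxonomy))
  abundance <- stage("io", read_otu_table(config$otu_table, taxonomy,
                                          top_k = config$top_k))
  G <- stage("io", read_genotypes(config$genotypes, abundance))
  abundance <- abundance[, rownames(G), drop = FALSE]
  covar <- NULL
  if (!is.null(config$covariates)) {
    cv <- read_tsv(config$covariates)
    covar <- as.matrix(cv[match(rownames(G), cv[[1]]), -1, drop = FALSE])
  }

  indices <- stage("networks", index_table(abundance, taxonomy,
                                           tau = config$tau,
                                           scope = config$scope))
  write_tsv(indices, file.path(out, "index_table.tsv"))

  hub_reports <- list()
  for (ty in interaction_types()) {
    net <- stage("hubs", consensus_network(abundance, taxonomy, ty,
                                           tau = config$tau[[ty]]))
    cent <- hub_centralities(net)
    write_tsv(cent, file.path(out, sprintf("centrality_%s.tsv", ty)))
    rep_ty <- detect_hubs(cent, type = ty, mode = config$hub_mode,
                          degree_cutoff = config$hub_degree,
                          closeness_cutoff = config$hub_closeness,
                          taxonomy = taxonomy)
    hub_reports[[ty]] <- rep_ty
    igraph::V(net)$hub <- igraph::V(net)$name %in% rep_ty$hubs$node
    write_network(net, file.path(out, sprintf("network_%s.graphml", ty)),
                  "graphml")
    write_network(net, file.path(out, sprintf("network_%s_edges.tsv", ty)),
                  "edgelist-tsv")
    write_tsv(rep_ty$hubs, file.path(out, sprintf("hubs_%s.tsv", ty)))
    ik <- interkingdom_edges(net)
    write_tsv(ik$interkingdom, file.path(out, sprintf("interkingdom_%s.tsv", ty)))
  }
  shared <- shared_hubs(hub_reports, taxonomy)
  write_tsv(shared$membership, file.path(out, "hub_membership.tsv"))

  scan <- stage("gwas", gwas_scan(indices, G, covariates = covar,
                                  min_maf = config$maf,
                                  threshold_logp = config$logp))
  all_res <- do.call(rbind, lapply(names(scan), function(ph) {
    cbind(phenotype = ph, scan[[ph]]$result)
  }))
  write_tsv(all_res, file.path(out, "gwas_results.tsv"))
  all_hits <- do.call(rbind, lapply(names(scan), function(ph) {
    h <- scan[[ph]]$hits
    if (nrow(h) == 0) NULL else cbind(phenotype = ph, h)
  }))
  if (is.null(all_hits)) {
    all_hits <- data.frame(phenotype = character(0), snp = character(0))
  }
  write_tsv(all_hits, file.path(out, "gwas_hits.tsv"))
  herit <- data.frame(
    phenotype = names(scan),
    lambda_gc = vapply(scan, function(s) s$lambda, numeric(1)),
    n_hits = vapply(scan, function(s) nrow(s$hits), numeric(1)),
    total_h2 = vapply(scan, function(s) s$heritability$total, numeric(1))
  )
  write_tsv(herit, file.path(out, "heritability.tsv"))

  qtl_nets <- list()
  Gf <- maf_filter(G[indices$host_id, , drop = FALSE], config$maf)
  for (ph in names(scan)) {
    hits <- scan[[ph]]$hits
    if (nrow(hits) < 2) next
    y <- log_phenotype(indices[[ph]])
    gm <- genotype_mean_transform(y, .impute_genotypes(
      Gf[, hits$snp, drop = FALSE], max_missing = 1))
    net <- stage("qtl_network",
                 learn_bn(gm, max_parents = config$max_parents,
                          restarts = config$restarts, seed = config$seed))
    qtl_nets[[ph]] <- net
    write_tsv(net$edges, file.path(out, sprintf("qtl_network_%s_edges.tsv", ph)))
  }
  hub_qtl_tab <- do.call(rbind, lapply(names(qtl_nets), function(ph) {
    h <- hub_qtls(qtl_nets[[ph]])
    if (length(h) == 0) NULL else data.frame(phenotype = ph, snp = h)
  }))
  if (is.null(hub_qtl_tab)) {
    hub_qtl_tab <- data.frame(phenotype = character(0), snp = character(0))
  }
  write_tsv(hub_qtl_tab, file.path(out, "hub_qtls.tsv"))

  manifest <- list(
    package = "micronetgwas",
    version = as.character(utils::packageVersion("micronetgwas")),
    parameters = config[setdiff(names(config), "out")],
    n_hosts = nrow(G), n_otus = nrow(abundance),
    n_snps_total = ncol(G), n_snps_after_maf = ncol(Gf),
    phenotypes = setdiff(names(indices), "host_id"),
    flagged_hosts = attr(indices, "flagged_hosts"),
    normalization_scope = config$scope,
    n_qtl_networks = length(qtl_nets)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(indices = indices, hubs = hub_reports, scan = scan,
                 qtl_networks = qtl_nets, manifest = manifest))
}
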