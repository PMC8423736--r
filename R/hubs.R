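# Hub-taxon calling: nodes jointly extreme in degree and closeness on the
# consensus network of each interaction type.

.hub_roles <- list(
  mutualism  = c(hub = "leaders",       other = "followers"),
  antagonism = c(hub = "antagonists",   other = "agonists"),
  aggression = c(hub = "hawks",         other = "doves"),
  altruism   = c(hub = "beneficiaries", other = "altruists")
)

#' Centralities for hub calling
#'
#' Hub status measures how embedded a taxon is in the co-occurrence
#' structure, not how far it can reach along directed edges: on directed
#' network types (aggression, altruism) the strongest nodes are edge sinks
#' whose out-closeness is 0, so a joint degree-and-closeness rule would never
#' fire. This helper therefore computes [node_centralities()] on the
#' underlying undirected topology (undirected graphs pass through unchanged),
#' mirroring the use of total degree for directed types.
#'
#' @param net igraph graph of either directedness.
#' @return data.frame as from [node_centralities()].
#' @export
hub_centralities <- function(net) {
  if (igraph::is_directed(net)) {
    net <- igraph::as_undirected(net, mode = "collapse")
  }
  node_centralities(net)
}

#' Detect hub taxa from a centrality table
#'
#' Hubs are the nodes strictly exceeding both a degree cutoff and a closeness
#' cutoff. Cutoffs may be absolute, or quantiles of each metric among
#' non-isolated nodes (default: the 0.90 quantile of each).
#'
#' @param centralities data.frame from [node_centralities()].
#' @param type Interaction type (fixes the role vocabulary: leaders,
#'   antagonists, hawks, beneficiaries vs followers, agonists, doves,
#'   altruists).
#' @param mode \code{"quantile"} or \code{"absolute"}.
#' @param degree_cutoff,closeness_cutoff Quantiles in [0, 1] (quantile mode)
#'   or absolute values.
#' @param taxonomy Optional annotation joined into the report.
#' @return List of class \code{"hub_report"}: type, mode, cutoffs actually
#'   applied, hubs data.frame (node, degree, closeness, kingdom, class) and
#'   role labels.
#' @export
detect_hubs <- function(centralities, type = "mutualism",
                        mode = c("quantile", "absolute"),
                        degree_cutoff = 0.90, closeness_cutoff = 0.90,
                        taxonomy = NULL) {
  mode <- match.arg(mode)
  non_iso <- centralities[centralities$degree > 0, , drop = FALSE]
  if (nrow(non_iso) == 0) {
    warning("all nodes isolated; empty hub set")
    cut_d <- Inf
    cut_c <- Inf
  } else if (mode == "quantile") {
    cut_d <- stats::quantile(non_iso$degree, degree_cutoff, names = FALSE)
    cut_c <- stats::quantile(non_iso$closeness, closeness_cutoff, names = FALSE)
  } else {
    cut_d <- degree_cutoff
    cut_c <- closeness_cutoff
  }
  is_hub <- centralities$degree > cut_d & centralities$closeness > cut_c
  hubs <- centralities[is_hub, c("node", "degree", "closeness"), drop = FALSE]
  if (!is.null(taxonomy)) {
    i <- match(hubs$node, taxonomy$otu_id)
    hubs$kingdom <- taxonomy$kingdom[i]
    hubs$class <- taxonomy$class[i]
    hubs$phylum <- taxonomy$phylum[i]
  }
  rownames(hubs) <- NULL
  structure(list(
    type = type, mode = mode,
    cutoffs = c(degree = cut_d, closeness = cut_c),
    roles = .hub_roles[[match.arg(type, interaction_types())]],
    hubs = hubs,
    all_nodes = centralities$node
  ), class = "hub_report")
}

#' @method print hub_report
#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("Hub report [%s]: %d hubs ('%s') of %d nodes; degree > %.3g, closeness > %.3g (%s mode)\n",
              x$type, nrow(x$hubs), x$roles[["hub"]], length(x$all_nodes),
              x$cutoffs[["degree"]], x$cutoffs[["closeness"]], x$mode))
  invisible(x)
}

#' Compare hub vs non-hub abundance
#'
#' Wilcoxon rank-sum test of mean log10 abundance across hosts, hubs vs
#' non-hubs. The one-sided alternative follows the report's role labels
#' (hubs more abundant); the two-sided p-value is reported alongside.
#'
#' @param report A [detect_hubs()] result with >= 1 hub.
#' @param abundance OTUs x hosts raw abundance matrix.
#' @return List: statistic, p_one_sided, p_two_sided, group_means.
#' @export
hub_abundance_test <- function(report, abundance) {
  mean_log <- rowMeans(transform_abundance(abundance))
  hub_ids <- report$hubs$node
  other_ids <- setdiff(rownames(abundance), hub_ids)
  a <- mean_log[intersect(hub_ids, names(mean_log))]
  b <- mean_log[other_ids]
  if (length(a) == 0 || length(b) == 0) {
    stop("undefined test: need at least one hub and one non-hub")
  }
  one <- stats::wilcox.test(a, b, alternative = "greater", exact = FALSE)
  two <- stats::wilcox.test(a, b, exact = FALSE)
  list(statistic = unname(one$statistic),
       p_one_sided = one$p.value, p_two_sided = two$p.value,
       group_means = c(hubs = mean(a), others = mean(b)))
}

#' Hub overlap across the four network types
#'
#' Per OTU, membership flags across the four reports; per phylum, pairwise
#' counts of phyla shared between the hub sets of two types.
#'
#' @param reports Named list of four [detect_hubs()] results (one per type).
#' @param taxonomy Taxonomy with a phylum column.
#' @return List: \code{membership} data.frame (otu x 4 logical columns) and
#'   \code{phylum_overlap} 4 x 4 symmetric matrix of shared-phylum counts.
#' @export
shared_hubs <- function(reports, taxonomy) {
  types <- names(reports)
  all_hubs <- sort(unique(unlist(lapply(reports, function(r) r$hubs$node))))
  memb <- sapply(reports, function(r) all_hubs %in% r$hubs$node)
  if (length(all_hubs) == 1) memb <- matrix(memb, 1, dimnames = list(NULL, types))
  membership <- data.frame(otu_id = all_hubs, memb, check.names = FALSE,
                           stringsAsFactors = FALSE)
  phyla <- lapply(reports, function(r) {
    unique(taxonomy$phylum[match(r$hubs$node, taxonomy$otu_id)])
  })
  ov <- matrix(0L, length(types), length(types), dimnames = list(types, types))
  for (i in seq_along(types)) {
    for (j in seq_along(types)) {
      ov[i, j] <- length(intersect(phyla[[i]], phyla[[j]]))
    }
  }
  list(membership = membership, phylum_overlap = ov)
}
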