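# Interaction networks and their emergent indices. Shortest-path centralities
# are computed on the unweighted topology (edges are present/absent after
# thresholding): BFS distances, Brandes' algorithm for betweenness, power
# iteration for PageRank, and the leading eigenvector of the (symmetrized)
# adjacency for eigencentrality.

#' Build an interaction network from a sparse edge set
#'
#' Nodes are every OTU in the abundance panel (isolated nodes kept).
#' Mutualism and antagonism networks are undirected; aggression and altruism
#' are directed from the more abundant to the less abundant member.
#'
#' @param sparse Edge data.frame from [threshold_matrix()].
#' @param taxonomy Taxonomy table for node annotation; unknown OTUs get
#'   kingdom "unknown" with a warning.
#' @param otu_ids Panel of node ids; defaults to the edge set's id universe
#'   (dimnames recorded by [interaction_matrix()]) or, failing that, the
#'   taxonomy's ids.
#' @return igraph graph with vertex attributes \code{name}, \code{kingdom},
#'   \code{class} and edge attribute \code{weight}; graph attributes
#'   \code{type} and \code{tau}.
#' @export
build_network <- function(sparse, taxonomy, otu_ids = NULL) {
  type <- attr(sparse, "type")
  directed <- type %in% c("aggression", "altruism")
  if (is.null(otu_ids)) otu_ids <- taxonomy$otu_id
  if (!is.null(sparse$u_id)) {
    el <- cbind(sparse$u_id, sparse$v_id)
  } else {
    el <- cbind(paste0("OTU_", sparse$u), paste0("OTU_", sparse$v))
  }
  idx <- match(otu_ids, taxonomy$otu_id)
  if (anyNA(idx)) warning("OTUs missing from taxonomy; kingdom set to unknown")
  verts <- data.frame(
    name = otu_ids,
    kingdom = ifelse(is.na(idx), "unknown", taxonomy$kingdom[idx]),
    class = ifelse(is.na(idx), "unknown", taxonomy$class[idx]),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      weight = sparse$weight, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = directed, vertices = verts)
  g <- igraph::set_graph_attr(g, "type", type)
  g <- igraph::set_graph_attr(g, "tau", attr(sparse, "tau"))
  g
}

# out-adjacency lists (for undirected graphs, all neighbors)
.adj_list <- function(net) {
  mode <- if (igraph::is_directed(net)) "out" else "all"
  lapply(igraph::adjacent_vertices(net, igraph::V(net), mode = mode),
         as.integer)
}

# single-source BFS + Brandes accumulation; returns distances and adds the
# source's dependency contribution to `bc`
.brandes_source <- function(adj, s, n) {
  dist <- rep(-1L, n)
  sigma <- numeric(n)
  dist[s] <- 0L
  sigma[s] <- 1
  pred <- vector("list", n)
  queue <- integer(n)
  queue[1] <- s
  head <- 1L
  tail <- 1L
  order_visited <- integer(0)
  while (head <= tail) {
    v <- queue[head]
    head <- head + 1L
    order_visited <- c(order_visited, v)
    for (w in adj[[v]]) {
      if (dist[w] < 0L) {
        dist[w] <- dist[v] + 1L
        tail <- tail + 1L
        queue[tail] <- w
      }
      if (dist[w] == dist[v] + 1L) {
        sigma[w] <- sigma[w] + sigma[v]
        pred[[w]] <- c(pred[[w]], v)
      }
    }
  }
  delta <- numeric(n)
  contrib <- numeric(n)
  for (w in rev(order_visited)) {
    for (v in pred[[w]]) {
      delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
    }
    if (w != s) contrib[w] <- delta[w]
  }
  list(dist = dist, contrib = contrib)
}

#' Node centralities of an interaction network
#'
#' Degree is the incident edge count (total in + out for directed graphs).
#' Closeness uses the Wasserman-Faust correction for disconnected graphs:
#' for a node reaching r others with total distance d, closeness is
#' \code{(r / d) * (r / (N - 1))}, and 0 for isolated nodes. Betweenness
#' counts shortest paths through a node (unweighted, no pair normalization).
#' Eccentricity is the largest distance to a reachable node (0 when none).
#' Eigencentrality is the leading eigenvector of the adjacency (symmetrized
#' for directed graphs) scaled to maximum 1; PageRank uses damping 0.85 with
#' dangling mass redistributed uniformly.
#'
#' @param net igraph graph (any, possibly disconnected).
#' @return data.frame with columns node, degree, closeness, betweenness,
#'   eccentricity, eigencentrality, pagerank.
#' @export
node_centralities <- function(net) {
  n <- igraph::vcount(net)
  directed <- igraph::is_directed(net)
  adj <- .adj_list(net)
  bc <- numeric(n)
  clo <- numeric(n)
  ecc <- numeric(n)
  for (s in seq_len(n)) {
    res <- .brandes_source(adj, s, n)
    bc <- bc + res$contrib
    d <- res$dist[-s]
    reach <- d[d > 0L]
    r <- length(reach)
    if (r > 0L && n > 1L) {
      clo[s] <- (r / sum(reach)) * (r / (n - 1))
      ecc[s] <- max(reach)
    }
  }
  if (!directed) bc <- bc / 2
  data.frame(
    node = igraph::V(net)$name %||% as.character(seq_len(n)),
    degree = as.numeric(igraph::degree(net, mode = "all")),
    closeness = clo,
    betweenness = bc,
    eccentricity = ecc,
    eigencentrality = .eigencentrality(net),
    pagerank = .pagerank(net),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.eigencentrality <- function(net) {
  n <- igraph::vcount(net)
  A <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  A <- (A + t(A) > 0) * 1          # symmetrize, topology only
  if (all(A == 0)) return(numeric(n))
  e <- eigen(A, symmetric = TRUE)
  v <- abs(e$vectors[, 1])
  v / max(v)
}

.pagerank <- function(net, damping = 0.85, tol = 1e-13, max_iter = 10000L) {
  n <- igraph::vcount(net)
  if (n == 0) return(numeric(0))
  A <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  if (!igraph::is_directed(net)) A <- (A + t(A) > 0) * 1
  outdeg <- rowSums(A)
  dangling <- outdeg == 0
  P <- A / ifelse(outdeg == 0, 1, outdeg)  # row-stochastic where defined
  pr <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    new <- (1 - damping) / n +
      damping * (as.numeric(crossprod(P, pr)) + sum(pr[dangling]) / n)
    if (sum(abs(new - pr)) < tol) {
      pr <- new
      break
    }
    pr <- new
  }
  pr
}

#' Emergent indices of one network
#'
#' Connectivity (Con) is the edge density: edges over possible edges given
#' the graph's directedness. The other five indices are the mean of the
#' corresponding node centrality over all nodes.
#'
#' @param net igraph graph.
#' @return Named numeric vector: Con, closeness, betweenness, eccentricity,
#'   eigencentrality, pagerank.
#' @export
emergent_indices <- function(net) {
  n <- igraph::vcount(net)
  possible <- if (igraph::is_directed(net)) n * (n - 1) else n * (n - 1) / 2
  cent <- node_centralities(net)
  c(Con = if (possible > 0) igraph::ecount(net) / possible else 0,
    closeness = mean(cent$closeness),
    betweenness = mean(cent$betweenness),
    eccentricity = mean(cent$eccentricity),
    eigencentrality = mean(cent$eigencentrality),
    pagerank = mean(cent$pagerank))
}

#' Host x index phenotype table
#'
#' For each host and each of the four interaction types, runs the full path
#' transform -> interaction matrix -> normalize -> threshold -> network ->
#' emergent indices, yielding 24 phenotype columns named
#' \code{<type>_<index>}. Hosts with fewer than two nonzero OTUs get all-zero
#' rows and are listed in the \code{flagged_hosts} attribute.
#'
#' @param abundance OTUs x hosts raw abundance matrix.
#' @param taxonomy Taxonomy table covering the panel.
#' @param tau Named list/vector of thresholds per type; defaults to the
#'   shipped 0.95/0.95/0.95/0.99.
#' @param scope \code{"per-host"} (each host's matrix min-max normalized on
#'   its own) or \code{"global"} (min-max computed over all hosts per type).
#' @return data.frame: host_id plus 24 numeric columns.
#' @export
index_table <- function(abundance, taxonomy, tau = NULL, scope = c("per-host", "global")) {
  scope <- match.arg(scope)
  types <- interaction_types()
  if (is.null(tau)) tau <- vapply(types, default_tau, numeric(1))
  hosts <- colnames(abundance)
  X <- transform_abundance(abundance)
  glob_rng <- NULL
  if (scope == "global") {
    glob_rng <- lapply(types, function(ty) {
      rng <- c(Inf, -Inf)
      for (h in hosts) {
        M <- interaction_matrix(X[, h], ty)
        v <- M[!is.na(M)]
        if (length(v)) rng <- c(min(rng[1], min(v)), max(rng[2], max(v)))
      }
      rng
    })
    names(glob_rng) <- types
  }
  cols <- as.vector(outer(c("Con", "closeness", "betweenness", "eccentricity",
                            "eigencentrality", "pagerank"),
                          types, function(i, t) paste(t, i, sep = "_")))
  out <- matrix(0, length(hosts), length(cols),
                dimnames = list(hosts, cols))
  flagged <- character(0)
  for (h in hosts) {
    x <- X[, h]
    if (sum(x > 0) < 2) {
      flagged <- c(flagged, h)
      next
    }
    for (ty in types) {
      M <- interaction_matrix(x, ty)
      if (scope == "global") {
        rng <- glob_rng[[ty]]
        if (is.finite(rng[1]) && rng[2] > rng[1]) {
          M[!is.na(M)] <- (M[!is.na(M)] - rng[1]) / (rng[2] - rng[1])
          M[!is.na(M)] <- pmin(pmax(M[!is.na(M)], 0), 1)
        } else {
          M[!is.na(M)] <- 0
        }
        attr(M, "scale") <- "normalized"
        attr(M, "type") <- ty
      } else {
        M <- normalize_matrix(M)
      }
      sp <- threshold_matrix(M, tau[[ty]])
      net <- build_network(sp, taxonomy, otu_ids = rownames(abundance))
      idx <- emergent_indices(net)
      out[h, paste(ty, names(idx), sep = "_")] <- idx
    }
  }
  df <- data.frame(host_id = hosts, out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "flagged_hosts") <- flagged
  attr(df, "scope") <- scope
  df
}

#' Consensus network across hosts
#'
#' Builds one network per interaction type from the across-host mean log10
#' abundances, through the same normalize/threshold path as per-host
#' networks. Used for hub calling.
#'
#' @inheritParams index_table
#' @param type Interaction type.
#' @param tau Threshold; defaults per type.
#' @return igraph graph.
#' @export
consensus_network <- function(abundance, taxonomy, type, tau = NULL) {
  x <- rowMeans(transform_abundance(abundance))
  sp <- sparse_interactions(x, type, tau)
  build_network(sp, taxonomy, otu_ids = rownames(abundance))
}

#' Compare node degree between kingdoms
#'
#' Two-sample Wilcoxon rank-sum test of node degree, bacteria vs fungi
#' (normal approximation with tie correction and continuity correction).
#'
#' @param net igraph graph with a kingdom vertex attribute.
#' @param taxonomy Unused when the graph carries kingdom annotations;
#'   otherwise consulted by node name.
#' @return List: statistic (W), p_value, medians (named, bacteria/fungi).
#' @export
kingdom_degree_test <- function(net, taxonomy = NULL) {
  kd <- igraph::V(net)$kingdom
  if (is.null(kd) && !is.null(taxonomy)) {
    kd <- taxonomy$kingdom[match(igraph::V(net)$name, taxonomy$otu_id)]
  }
  deg <- as.numeric(igraph::degree(net, mode = "all"))
  db <- deg[kd == "bacteria"]
  df <- deg[kd == "fungi"]
  if (length(db) == 0 || length(df) == 0) {
    stop("undefined test: both kingdoms must be present")
  }
  if (stats::sd(c(db, df)) == 0) {
    # every node has the same degree: no evidence against the null
    return(list(statistic = length(db) * length(df) / 2, p_value = 1,
                medians = c(bacteria = stats::median(db),
                            fungi = stats::median(df))))
  }
  wt <- stats::wilcox.test(db, df, exact = FALSE, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       medians = c(bacteria = stats::median(db), fungi = stats::median(df)))
}

#' Tabulate interkingdom edges by taxonomic class
#'
#' Counts bacteria-fungi edges grouped by (bacterial class, fungal class),
#' sorted by count descending; within-kingdom edge totals are tabulated
#' separately.
#'
#' @param net igraph graph with kingdom/class vertex attributes.
#' @return List: \code{interkingdom} data.frame (bacterial_class,
#'   fungal_class, n_edges) and \code{within} named counts.
#' @export
interkingdom_edges <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0) {
    return(list(
      interkingdom = data.frame(bacterial_class = character(0),
                                fungal_class = character(0),
                                n_edges = integer(0)),
      within = c(bacteria = 0L, fungi = 0L)))
  }
  v <- igraph::V(net)$name
  kd <- igraph::V(net)$kingdom[match(el, v)]
  cl <- igraph::V(net)$class[match(el, v)]
  dim(kd) <- dim(cl) <- dim(el)
  inter <- xor(kd[, 1] == "bacteria", kd[, 2] == "bacteria") &
    (kd[, 1] %in% c("bacteria", "fungi")) & (kd[, 2] %in% c("bacteria", "fungi"))
  within <- c(bacteria = sum(kd[, 1] == "bacteria" & kd[, 2] == "bacteria"),
              fungi = sum(kd[, 1] == "fungi" & kd[, 2] == "fungi"))
  if (!any(inter)) {
    return(list(interkingdom = data.frame(bacterial_class = character(0),
                                          fungal_class = character(0),
                                          n_edges = integer(0)),
                within = within))
  }
  bc <- ifelse(kd[inter, 1] == "bacteria", cl[inter, 1], cl[inter, 2])
  fc <- ifelse(kd[inter, 1] == "fungi", cl[inter, 1], cl[inter, 2])
  tab <- stats::aggregate(list(n_edges = rep(1L, length(bc))),
                          by = list(bacterial_class = bc, fungal_class = fc),
                          FUN = sum)
  tab <- tab[order(-tab$n_edges, tab$bacterial_class, tab$fungal_class), ]
  rownames(tab) <- NULL
  list(interkingdom = tab, within = within)
}
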