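# Epistatic QTL networks: score-based Bayesian-network structure learning
# over genotype-mean-transformed phenotype columns of the significant SNPs.
# Score is the decomposable Gaussian BIC; search is greedy hill climbing over
# add/delete/reverse moves with random restarts, acyclicity enforced at every
# move.

#' Genotype-mean transform of a phenotype
#'
#' For each significant SNP, every host is assigned the mean phenotype of all
#' hosts sharing its genotype at that SNP, turning the SNP-phenotype data
#' into a hosts x SNPs matrix of genotype means (two distinct values per
#' biallelic column).
#'
#' @param y Phenotype vector aligned to genotype rows.
#' @param hits_G Hosts x significant-SNPs genotype matrix.
#' @return Numeric matrix of the same shape as \code{hits_G}; monomorphic
#'   columns are constant and listed in the \code{monomorphic} attribute.
#' @export
genotype_mean_transform <- function(y, hits_G) {
  if (length(y) != nrow(hits_G)) stop("phenotype and genotypes must align")
  out <- apply(hits_G, 2, function(x) stats::ave(y, x, FUN = mean))
  dimnames(out) <- dimnames(hits_G)
  mono <- colnames(out)[apply(hits_G, 2, function(x) length(unique(x)) < 2)]
  attr(out, "monomorphic") <- mono
  out
}

.is_acyclic <- function(adj) {
  # Kahn's topological sort on adjacency matrix (adj[i,j] = edge i -> j)
  n <- nrow(adj)
  indeg <- colSums(adj)
  active <- rep(TRUE, n)
  repeat {
    src <- which(active & indeg == 0)
    if (length(src) == 0) break
    for (s in src) {
      indeg <- indeg - adj[s, ]
      active[s] <- FALSE
    }
  }
  !any(active)
}

# Gaussian BIC local score of one node given its parents
.local_score <- function(data, child, parents, n) {
  y <- data[, child]
  if (length(parents) == 0) {
    res <- y - mean(y)
    k <- 2
  } else {
    fit <- stats::lm.fit(cbind(1, data[, parents, drop = FALSE]), y)
    res <- fit$residuals
    k <- length(parents) + 2
  }
  sigma2 <- max(sum(res^2) / n, 1e-300)
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  loglik - 0.5 * log(n) * k
}

#' Score a DAG by Gaussian BIC
#'
#' Sum over nodes of the log-likelihood of each node regressed on its
#' parents minus the BIC penalty (0.5 log n per parameter); higher is
#' better. Decomposable by node.
#'
#' @param data Hosts x nodes numeric matrix (genotype means).
#' @param adj Square 0/1 adjacency matrix, \code{adj[i, j] = 1} for an edge
#'   i -> j; must be acyclic.
#' @return Scalar score.
#' @export
score_dag <- function(data, adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(data)) stop("adjacency must match data columns")
  if (!.is_acyclic(adj)) stop("structure error: graph is cyclic")
  n <- nrow(data)
  sum(vapply(seq_len(ncol(data)), function(j) {
    .local_score(data, j, which(adj[, j] == 1), n)
  }, numeric(1)))
}

#' Learn a QTL network by hill climbing
#'
#' Greedy search over add/delete/reverse edge moves maximizing the Gaussian
#' BIC, with random restarts from sparse random DAGs; the best-scoring DAG
#' over all restarts is returned. Constant columns are excluded with a
#' warning. Deterministic given \code{seed}.
#'
#' @param data Hosts x SNPs genotype-mean matrix.
#' @param max_parents Parent cap per node (default 3).
#' @param restarts Number of random restarts after the empty-graph start.
#' @param seed RNG seed.
#' @return List of class \code{"qtl_network"}: nodes, adjacency, edge list
#'   data.frame (from, to), score.
#' @export
learn_bn <- function(data, max_parents = 3, restarts = 10, seed = 1) {
  keep <- apply(data, 2, function(x) stats::sd(x) > 0)
  if (any(!keep)) {
    warning(sprintf("%d constant columns excluded", sum(!keep)))
  }
  data <- data[, keep, drop = FALSE]
  p <- ncol(data)
  nodes <- colnames(data) %||% paste0("V", seq_len(p))
  if (p < 2) {
    return(structure(list(nodes = nodes,
                          adjacency = matrix(0, p, p, dimnames = list(nodes, nodes)),
                          edges = data.frame(from = character(0), to = character(0)),
                          score = if (p == 1) score_dag(data, matrix(0, 1, 1)) else 0),
                     class = "qtl_network"))
  }
  n <- nrow(data)
  set.seed(seed)
  climb <- function(adj) {
    local <- vapply(seq_len(p), function(j) {
      .local_score(data, j, which(adj[, j] == 1), n)
    }, numeric(1))
    repeat {
      best_gain <- 1e-9
      best_move <- NULL
      for (i in seq_len(p)) {
        for (j in seq_len(p)) {
          if (i == j) next
          if (adj[i, j] == 0) {
            # add i -> j
            if (sum(adj[, j]) >= max_parents || adj[j, i] == 1) next
            adj[i, j] <- 1
            if (.is_acyclic(adj)) {
              new_j <- .local_score(data, j, which(adj[, j] == 1), n)
              gain <- new_j - local[j]
              if (gain > best_gain) {
                best_gain <- gain
                best_move <- list(kind = "add", i = i, j = j, new_j = new_j)
              }
            }
            adj[i, j] <- 0
          } else {
            # delete i -> j
            adj[i, j] <- 0
            new_j <- .local_score(data, j, which(adj[, j] == 1), n)
            gain <- new_j - local[j]
            if (gain > best_gain) {
              best_gain <- gain
              best_move <- list(kind = "delete", i = i, j = j, new_j = new_j)
            }
            # reverse to j -> i
            if (sum(adj[, i]) < max_parents) {
              adj[j, i] <- 1
              if (.is_acyclic(adj)) {
                new_i <- .local_score(data, i, which(adj[, i] == 1), n)
                gain <- (new_j - local[j]) + (new_i - local[i])
                if (gain > best_gain) {
                  best_gain <- gain
                  best_move <- list(kind = "reverse", i = i, j = j,
                                    new_j = new_j, new_i = new_i)
                }
              }
              adj[j, i] <- 0
            }
            adj[i, j] <- 1
          }
        }
      }
      if (is.null(best_move)) break
      i <- best_move$i
      j <- best_move$j
      if (best_move$kind == "add") {
        adj[i, j] <- 1
        local[j] <- best_move$new_j
      } else if (best_move$kind == "delete") {
        adj[i, j] <- 0
        local[j] <- best_move$new_j
      } else {
        adj[i, j] <- 0
        adj[j, i] <- 1
        local[j] <- best_move$new_j
        local[i] <- best_move$new_i
      }
    }
    list(adj = adj, score = sum(local))
  }
  random_dag <- function() {
    ord <- sample(p)
    adj <- matrix(0, p, p)
    for (a in seq_len(p - 1)) {
      for (b in seq((a + 1), p)) {
        if (stats::runif(1) < 0.2 && sum(adj[, ord[b]]) < max_parents) {
          adj[ord[a], ord[b]] <- 1
        }
      }
    }
    adj
  }
  best <- climb(matrix(0, p, p))
  for (r in seq_len(restarts)) {
    cand <- climb(random_dag())
    if (cand$score > best$score + 1e-12) best <- cand
  }
  adj <- best$adj
  dimnames(adj) <- list(nodes, nodes)
  idx <- which(adj == 1, arr.ind = TRUE)
  edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, adjacency = adj, edges = edges,
                 score = best$score),
            class = "qtl_network")
}

#' @method print qtl_network
#' @export
print.qtl_network <- function(x, ...) {
  cat(sprintf("QTL network: %d nodes, %d directed edges, BIC score %.3f\n",
              length(x$nodes), nrow(x$edges), x$score))
  invisible(x)
}

#' Hub QTLs of a learned network
#'
#' Nodes whose total degree (in + out) strictly exceeds the q-quantile of
#' degrees among non-isolated nodes; an absolute cutoff may be given instead.
#'
#' @param net A [learn_bn()] result.
#' @param quantile Degree quantile in [0, 1] (default 0.90).
#' @param absolute Optional absolute degree cutoff overriding the quantile.
#' @return Character vector of hub SNP ids (empty for edgeless networks).
#' @export
hub_qtls <- function(net, quantile = 0.90, absolute = NULL) {
  deg <- rowSums(net$adjacency) + colSums(net$adjacency)
  non_iso <- deg[deg > 0]
  if (length(non_iso) == 0) return(character(0))
  cutoff <- if (!is.null(absolute)) absolute else {
    stats::quantile(non_iso, quantile, names = FALSE)
  }
  names(deg)[deg > cutoff & deg > 0]
}

#' Convert a QTL network to igraph
#' @param net A [learn_bn()] result.
#' @return Directed igraph object (hub flag as vertex attribute).
#' @export
qtl_network_graph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = data.frame(name = net$nodes))
  igraph::V(g)$hub <- igraph::V(g)$name %in% hub_qtls(net)
  g
}
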