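# Independent brute-force oracles used to validate graph computations.
# These deliberately use different algorithms than the package: Floyd-Warshall
# for distances, exhaustive simple-path enumeration for betweenness, and a
# dense linear solve for PageRank.

oracle_distances <- function(A, directed) {
  n <- nrow(A)
  if (!directed) A <- (A + t(A) > 0) * 1
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_closeness <- function(A, directed) {
  D <- oracle_distances(A, directed)
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d) & d > 0]
    r <- length(d)
    if (r == 0 || n == 1) 0 else (r / sum(d)) * (r / (n - 1))
  }, numeric(1))
}

oracle_eccentricity <- function(A, directed) {
  D <- oracle_distances(A, directed)
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d) & d > 0]
    if (length(d) == 0) 0 else max(d)
  }, numeric(1))
}

# all simple paths from s to t, by depth-first enumeration
.all_simple_paths <- function(A, s, t) {
  n <- nrow(A)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (w in which(A[v, ] == 1)) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(s)
  paths
}

oracle_betweenness <- function(A, directed) {
  n <- nrow(A)
  if (n < 2) return(numeric(n))
  if (!directed) A <- (A + t(A) > 0) * 1
  bc <- numeric(n)
  pairs <- if (directed) {
    expand.grid(s = seq_len(n), t = seq_len(n))
  } else {
    do.call(rbind, lapply(seq_len(n), function(s) {
      if (s < n) data.frame(s = s, t = (s + 1):n) else NULL
    }))
  }
  for (k in seq_len(nrow(pairs))) {
    s <- pairs$s[k]
    t <- pairs$t[k]
    if (s == t) next
    paths <- .all_simple_paths(A, s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, length, integer(1))
    shortest <- paths[lens == min(lens)]
    if (min(lens) <= 2) next   # direct edge: no intermediates
    through <- table(unlist(lapply(shortest, function(p) p[-c(1, length(p))])))
    bc[as.integer(names(through))] <- bc[as.integer(names(through))] +
      as.numeric(through) / length(shortest)
  }
  bc
}

oracle_pagerank <- function(A, directed, damping = 0.85) {
  n <- nrow(A)
  if (!directed) A <- (A + t(A) > 0) * 1
  outdeg <- rowSums(A)
  P <- A / ifelse(outdeg == 0, 1, outdeg)
  P[outdeg == 0, ] <- 1 / n   # dangling: uniform
  # pr = (1-d)/n * 1 + d * t(P) pr  =>  (I - d t(P)) pr = (1-d)/n
  unname(solve(diag(n) - damping * t(P), rep((1 - damping) / n, n)))
}

# every labeled DAG on p nodes, as a list of adjacency matrices
enumerate_dags <- function(p) {
  slots <- which(diag(p) == 0)   # off-diagonal cells, column-major
  k <- length(slots)
  out <- list()
  is_acyclic_oracle <- function(adj) {
    # a directed graph has a cycle iff diag(A^k) > 0 for some k <= p
    M <- adj
    for (i in seq_len(p)) {
      if (any(diag(M) > 0)) return(FALSE)
      M <- M %*% adj
    }
    TRUE
  }
  for (mask in 0:(2^k - 1)) {
    adj <- matrix(0, p, p)
    bits <- bitwAnd(bitwShiftR(mask, 0:(k - 1)), 1L)
    adj[slots] <- bits
    if (is_acyclic_oracle(adj)) out[[length(out) + 1]] <- adj
  }
  out
}

# igraph object from a 0/1 adjacency matrix
graph_from_adj <- function(A, directed) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = if (directed) "directed" else "undirected")
  igraph::V(g)$name <- paste0("n", seq_len(nrow(A)))
  g
}

# small deterministic synthetic study shared across tests
tiny_study <- function(seed = 42, n_hosts = 30, n_otus_per_kingdom = 10,
                       n_snps = 100, ...) {
  cfg <- simulation_config(n_hosts = n_hosts,
                           n_bacteria = n_otus_per_kingdom,
                           n_fungi = n_otus_per_kingdom,
                           n_snps = n_snps, seed = seed, ...)
  simulate_dataset(cfg)
}
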