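make_tax <- function(ids, kingdom = "bacteria", class = "c1", phylum = "p1") {
  data.frame(otu_id = ids, kingdom = kingdom, phylum = phylum, class = class,
             stringsAsFactors = FALSE)
}

test_that("build_network keeps isolated nodes and applies the direction rule", {
  sim <- tiny_study(seed = 8)
  x <- transform_abundance(sim$abundance[, 1])
  # empty sparse matrix -> all-node zero-edge graph
  empty <- data.frame(u = integer(0), v = integer(0), weight = numeric(0),
                      u_id = character(0), v_id = character(0))
  attr(empty, "type") <- "mutualism"; attr(empty, "tau") <- 0.95
  g0 <- build_network(empty, sim$taxonomy, otu_ids = rownames(sim$abundance))
  expect_equal(igraph::vcount(g0), 20)
  expect_equal(igraph::ecount(g0), 0)

  # one retained pair: directed u -> v for aggression, undirected for mutualism
  tx <- make_tax(c("A", "B"))
  sp <- data.frame(u = 1L, v = 2L, weight = 1, u_id = "A", v_id = "B")
  attr(sp, "type") <- "aggression"; attr(sp, "tau") <- 0.95; attr(sp, "m") <- 2L
  ga <- build_network(sp, tx, otu_ids = c("A", "B"))
  expect_true(igraph::is_directed(ga))
  expect_equal(igraph::as_edgelist(ga)[1, ], c("A", "B"))
  attr(sp, "type") <- "mutualism"
  gm <- build_network(sp, tx, otu_ids = c("A", "B"))
  expect_false(igraph::is_directed(gm))
  expect_warning(build_network(sp, make_tax("A"), otu_ids = c("A", "B")),
                 "unknown")
})

test_that("path-graph centralities match the hand-derived values", {
  g <- igraph::make_graph(c("a", "b", "b", "c"), directed = FALSE)
  ct <- node_centralities(g)
  expect_equal(ct$degree, c(1, 2, 1))
  expect_equal(ct$closeness, c(2 / 3, 1, 2 / 3))
  expect_equal(ct$betweenness, c(0, 1, 0))
  expect_equal(ct$eccentricity, c(2, 1, 2))
})

test_that("triangle and edgeless graphs hit the symmetry conventions", {
  tri <- igraph::make_ring(3)
  ct <- node_centralities(tri)
  expect_equal(ct$pagerank, rep(1 / 3, 3), tolerance = 1e-10)
  expect_equal(ct$eigencentrality, rep(1, 3), tolerance = 1e-10)
  g0 <- igraph::make_empty_graph(4, directed = FALSE)
  ct0 <- node_centralities(g0)
  expect_true(all(ct0$degree == 0 & ct0$closeness == 0 &
                    ct0$betweenness == 0 & ct0$eccentricity == 0 &
                    ct0$eigencentrality == 0))
  expect_equal(ct0$pagerank, rep(1 / 4, 4), tolerance = 1e-12)
})

test_that("centralities agree with igraph on random graphs", {
  set.seed(99)
  for (r in 1:20) {
    directed <- r %% 2 == 0
    g <- igraph::sample_gnp(sample(4:9, 1), 0.35, directed = directed)
    igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
    ct <- node_centralities(g)
    expect_equal(ct$betweenness,
                 unname(igraph::betweenness(g, directed = directed, weights = NA)),
                 tolerance = 1e-9)
    expect_equal(ct$pagerank,
                 unname(igraph::page_rank(g, damping = 0.85, weights = NA)$vector),
                 tolerance = 1e-8)
    if (igraph::is_connected(g, mode = "strong")) {
      expect_equal(ct$closeness,
                   unname(igraph::closeness(g, mode = "out", normalized = TRUE,
                                            weights = NA)),
                   tolerance = 1e-10)
      expect_equal(ct$eccentricity,
                   unname(igraph::eccentricity(
                     g, mode = if (directed) "out" else "all")))
      if (!directed) {
        expect_equal(ct$eigencentrality,
                     unname(igraph::eigen_centrality(g, weights = NA)$vector),
                     tolerance = 1e-7)
      }
    }
  }
})

test_that("emergent indices implement density plus mean-over-node conventions", {
  g2 <- igraph::make_graph(c("a", "b"), directed = FALSE)
  expect_equal(emergent_indices(g2)[["Con"]], 1)
  g0 <- igraph::make_empty_graph(5, directed = FALSE)
  idx0 <- emergent_indices(g0)
  expect_equal(idx0[["Con"]], 0)
  expect_equal(idx0[["closeness"]], 0)
  tri <- igraph::make_ring(3)
  expect_equal(emergent_indices(tri)[["pagerank"]], 1 / 3, tolerance = 1e-10)
  # Con reflects topology only, not edge weights
  igraph::E(tri)$weight <- c(10, 0.2, 3)
  expect_equal(emergent_indices(tri)[["Con"]], 1)
})

test_that("index_table is deterministic and invariant to host and OTU order", {
  sim <- tiny_study(seed = 12, n_hosts = 6, n_otus_per_kingdom = 5)
  ab <- sim$abundance
  ab[, 2] <- ab[, 1]  # two hosts with identical abundance vectors
  it <- index_table(ab, sim$taxonomy)
  expect_equal(unlist(it[1, -1]), unlist(it[2, -1]))
  expect_equal(dim(it), c(6, 25))

  # permuting OTU rows leaves every index unchanged
  perm <- sample(nrow(ab))
  it_p <- index_table(ab[perm, ], sim$taxonomy)
  expect_equal(it_p[, -1], it[, -1], tolerance = 1e-12)

  # permuting host columns permutes rows correspondingly
  hperm <- c(3, 1, 2, 6, 5, 4)
  it_h <- index_table(ab[, hperm], sim$taxonomy)
  expect_equal(it_h[, -1], it[hperm, -1], ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("hosts with fewer than two nonzero OTUs are zeroed and flagged", {
  sim <- tiny_study(seed = 13, n_hosts = 4, n_otus_per_kingdom = 3)
  ab <- sim$abundance
  ab[, 2] <- 0
  ab[1, 2] <- 5
  it <- index_table(ab, sim$taxonomy)
  expect_equal(attr(it, "flagged_hosts"), colnames(ab)[2])
  expect_true(all(unlist(it[2, -1]) == 0))
})

test_that("kingdom degree comparison behaves under null, separation and label swap", {
  tx <- make_tax(paste0("O", 1:20),
                 kingdom = rep(c("bacteria", "fungi"), each = 10))
  # identical degree multisets: two disjoint 10-node rings
  g <- igraph::make_ring(10)
  igraph::V(g)$name <- paste0("O", 1:10)
  h <- igraph::make_ring(10)
  igraph::V(h)$name <- paste0("O", 11:20)
  gu <- igraph::disjoint_union(g, h)
  igraph::V(gu)$kingdom <- tx$kingdom[match(igraph::V(gu)$name, tx$otu_id)]
  null_res <- kingdom_degree_test(gu)
  expect_gt(null_res$p_value, 0.9)

  # bacteria all degree 5 (K6 components), fungi all isolated
  k6a <- igraph::make_full_graph(6)
  igraph::V(k6a)$name <- paste0("O", 1:6)
  k6b <- igraph::make_full_graph(6)
  igraph::V(k6b)$name <- paste0("O", 7:12)
  iso <- igraph::make_empty_graph(10, directed = FALSE)
  igraph::V(iso)$name <- paste0("F", 1:10)
  gsep <- igraph::disjoint_union(k6a, k6b, iso)
  igraph::V(gsep)$kingdom <- c(rep("bacteria", 12), rep("fungi", 10))
  sep <- kingdom_degree_test(gsep)
  expect_lt(sep$p_value, 0.001)
  expect_equal(unname(sep$medians), c(5, 0))

  # swapping labels keeps the p-value, flips the medians
  igraph::V(gsep)$kingdom <- c(rep("fungi", 12), rep("bacteria", 10))
  swp <- kingdom_degree_test(gsep)
  expect_equal(swp$p_value, sep$p_value, tolerance = 1e-12)
  expect_equal(unname(swp$medians), c(0, 5))

  igraph::V(gsep)$kingdom <- "bacteria"
  expect_error(kingdom_degree_test(gsep), "both kingdoms")
})

test_that("interkingdom edge counts are conserved and sorted", {
  tx <- data.frame(otu_id = c("B1", "B2", "F1", "F2"),
                   kingdom = c("bacteria", "bacteria", "fungi", "fungi"),
                   phylum = "p",
                   class = c("Actino", "Beta", "Leotio", "Dothideo"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("B1", "B1", "B2", "B2"),
               to = c("B2", "F1", "F1", "F2")),
    directed = FALSE,
    vertices = data.frame(name = tx$otu_id, kingdom = tx$kingdom,
                          class = tx$class))
  ik <- interkingdom_edges(g)
  expect_equal(sum(ik$interkingdom$n_edges), 3)
  expect_equal(unname(ik$within["bacteria"]), 1L)
  expect_true(all(diff(ik$interkingdom$n_edges) <= 0))
  g0 <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(g0)$name <- c("B1", "F1")
  igraph::V(g0)$kingdom <- c("bacteria", "fungi")
  igraph::V(g0)$class <- c("a", "b")
  expect_equal(nrow(interkingdom_edges(g0)$interkingdom), 0)
})
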