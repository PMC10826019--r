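clique_edges <- function(ids, conf = 900) {
  pr <- t(utils::combn(ids, 2))
  edge_table(pr[, 1], pr[, 2], rep(conf, nrow(pr)))
}

test_that("graph construction: threshold, loops, duplicates, components", {
  e <- edge_table(c("A", "A"), c("B", "C"), c(400, 399))
  g <- build_graph(e)
  expect_setequal(igraph::V(g)$name, c("A", "B"))
  expect_equal(igraph::ecount(g), 1)

  e2 <- edge_table(c("A", "A", "B"), c("A", "B", "A"), c(900, 500, 700))
  g2 <- build_graph(e2)
  expect_equal(igraph::ecount(g2), 1)
  expect_equal(igraph::E(g2)$confidence, 700)

  # Small fragments are dropped by default, kept on request.
  e3 <- rbind(clique_edges(c("A", "B", "C", "D")),
              edge_table("X", "Y", 900))
  expect_setequal(igraph::V(build_graph(e3))$name, c("A", "B", "C", "D"))
  expect_equal(igraph::vcount(build_graph(e3, largest_component = FALSE)), 6)

  expect_error(build_graph(edge_table("A", "B", 100)), "threshold")
})

test_that("MCODE vertex weights follow the k-core x density rule", {
  g <- build_graph(clique_edges(sprintf("C%d", 1:5)))
  w <- mcode_vertex_weights(g)
  expect_equal(unname(w), rep(4, 5))  # 4-core of the closed nbhd, density 1

  path <- build_graph(edge_table(c("A", "B", "C"), c("B", "C", "D"),
                                 rep(900, 3)))
  expect_equal(unname(mcode_vertex_weights(path)), rep(0, 4))

  tri <- build_graph(clique_edges(c("A", "B", "C")))
  expect_equal(unname(mcode_vertex_weights(tri)), rep(0, 3))
})

test_that("MCODE recovers hand-run cluster fixtures", {
  # 5-clique plus a pendant: one cluster, the clique, score 5.
  g1 <- build_graph(rbind(clique_edges(sprintf("C%d", 1:5)),
                          edge_table("C1", "PEND", 900)))
  m1 <- mcode_find_clusters(g1)
  expect_length(m1$clusters, 1)
  expect_setequal(m1$clusters[[1]], sprintf("C%d", 1:5))
  expect_equal(m1$scores, 5)

  # A triangle has no 3-core: no clusters.
  expect_length(mcode_find_clusters(build_graph(
    clique_edges(c("A", "B", "C"))))$clusters, 0)

  # Two 4-cliques joined by a bridge: two clusters of four.
  g3 <- build_graph(rbind(clique_edges(sprintf("A%d", 1:4)),
                          clique_edges(sprintf("B%d", 1:4)),
                          edge_table("A1", "B1", 900)))
  m3 <- mcode_find_clusters(g3)
  expect_length(m3$clusters, 2)
  expect_setequal(m3$clusters[[1]], sprintf("A%d", 1:4))
  expect_setequal(m3$clusters[[2]], sprintf("B%d", 1:4))
})

test_that("clusters contain a k-core and scores recompute from scratch", {
  for (s in 1:5) {
    sp <- synth_ppi(80, c(7, 5, 4), 0.03, seed = s)
    g <- build_graph(sp$edges)
    m <- mcode_find_clusters(g)
    seen <- character()
    for (i in seq_along(m$clusters)) {
      cl <- m$clusters[[i]]
      expect_length(intersect(cl, seen), 0)      # disjoint
      seen <- c(seen, cl)
      sub <- igraph::induced_subgraph(g, cl)
      expect_gte(max(igraph::coreness(sub)), 3)  # independent k-core check
      n <- igraph::vcount(sub)
      dens <- 2 * igraph::ecount(sub) / (n * (n - 1))
      expect_equal(m$scores[i], dens * n, tolerance = 1e-12)
    }
    expect_true(all(diff(m$scores) <= 1e-12))    # decreasing score order
  }
})

test_that("centralities match closed-form values on canonical graphs", {
  path <- build_graph(edge_table(c("A", "B"), c("B", "C"), rep(900, 2)))
  tp <- centralities(path)
  expect_equal(tp$betweenness[tp$node == "B"], 1)
  expect_equal(tp$closeness[tp$node == "B"], 1)
  expect_equal(tp$closeness[tp$node == "A"], 2 / 3)

  cyc <- build_graph(edge_table(c("A", "B", "C", "D"),
                                c("B", "C", "D", "A"), rep(900, 4)))
  tc <- centralities(cyc)
  expect_equal(tc$betweenness, rep(0.5 / 3, 4), tolerance = 1e-12)

  star <- build_graph(edge_table(rep("HUB", 5), sprintf("L%d", 1:5),
                                 rep(900, 5)))
  ts <- centralities(star)
  expect_equal(ts$betweenness[ts$node == "HUB"], 1)
  expect_equal(ts$degree[ts$node == "HUB"], 5)
})

test_that("centralities agree with the brute-force oracle on random graphs", {
  for (s in 1:20) {
    e <- rand_graph_edges(sample(8:30, 1), runif(1, 0.1, 0.35), seed = s)
    g <- build_graph(e, largest_component = FALSE)
    got <- centralities(g)
    want <- oracle_centralities(e)
    got <- got[order(got$node), ]
    want <- want[order(want$node), ]
    expect_equal(got$degree, want$degree)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-9)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-9)
  }
})

test_that("hub ranking aggregates ranks and breaks ties deterministically", {
  star <- build_graph(edge_table(rep("HUB", 4), sprintf("L%d", 1:4),
                                 rep(900, 4)))
  topo <- centralities(star)
  expect_identical(rank_hubs(topo, 1), "HUB")
  # Leaves are automorphic: order among them is by id.
  expect_identical(rank_hubs(topo, 5), c("HUB", sprintf("L%d", 1:4)))
  expect_error(rank_hubs(topo, 9), "exceeds")
})

test_that("the planted hub is ranked first across seeds", {
  hits <- vapply(1:20, function(s) {
    sp <- synth_ppi(100, c(8, 6, 5), 0.02, seed = s)
    g <- build_graph(sp$edges)
    rank_hubs(centralities(g), 1) == sp$truth$hub_gene
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
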