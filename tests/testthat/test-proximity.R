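path_graph <- function() {
  build_graph(edge_table(c("A", "B", "C"), c("B", "C", "D"), rep(900, 3)))
}

test_that("weighted distance matches hand-computed path-graph cases", {
  g <- path_graph()
  expect_equal(weighted_distance(g, "A", "D")$d, 3)
  expect_equal(weighted_distance(g, "A", c("B", "D"))$d, 2)
  e <- build_graph(edge_table("A", "B", 900))
  expect_equal(weighted_distance(e, "A", "A")$d, -log(2), tolerance = 1e-12)
  # Off-network targets are counted, not scored.
  r <- weighted_distance(g, "A", c("D", "ZZ"))
  expect_equal(r$d, 3); expect_equal(r$n_used, 1)
  expect_equal(r$n_off_network, 1)
})

test_that("the self-target bound holds: targets inside S give d <= 0", {
  for (s in 1:5) {
    sp <- synth_ppi(60, c(6, 5), 0.03, seed = s)
    g <- build_graph(sp$edges)
    S <- intersect(sp$truth$modules[[1]], igraph::V(g)$name)
    expect_lte(weighted_distance(g, S, sample(S, 3))$d, 0)
  }
})

test_that("weighted distance equals the literal formula on random graphs", {
  set.seed(53)
  for (s in 1:25) {
    e <- rand_graph_edges(sample(8:25, 1), runif(1, 0.12, 0.3), seed = s + 100)
    g <- build_graph(e, largest_component = FALSE)
    nodes <- igraph::V(g)$name
    S <- sample(nodes, sample(2:4, 1))
    targets <- sample(nodes, sample(2:5, 1))
    got <- weighted_distance(g, S, targets)
    want <- oracle_weighted_distance(e, S, targets)
    expect_equal(got$d, want$d, tolerance = 1e-12)
    expect_equal(got$n_used, want$n_used)
  }
})

test_that("the permutation null is deterministic and sized correctly", {
  g <- path_graph()
  n1 <- null_distribution(g, "A", 2, n_perm = 50, seed = 3)
  expect_length(n1, 50)
  expect_identical(n1, null_distribution(g, "A", 2, n_perm = 50, seed = 3))
  expect_false(identical(n1, null_distribution(g, "A", 2, 50, seed = 4)))
  expect_error(null_distribution(g, "A", 99, 10, seed = 1), "exceeds")
})

test_that("on a cycle the null reproduces enumerated distance frequencies", {
  m <- 9
  ids <- sprintf("V%d", 1:m)
  g <- build_graph(edge_table(ids, ids[c(2:m, 1)], rep(900, m)))
  null <- null_distribution(g, ids[1], 1, n_perm = 2000, seed = 5)
  # Exact distribution: distance 0 w.p. 1/9; 1..4 w.p. 2/9 each
  # (distance 0 carries the self-target weight -ln(2+1)).
  expected <- c(`0` = 1, `1` = 2, `2` = 2, `3` = 2, `4` = 2) / m
  vals <- ifelse(null < 0, 0, null)
  for (d in names(expected)) {
    p <- expected[[d]]
    se <- sqrt(p * (1 - p) / 2000)
    expect_lt(abs(mean(vals == as.numeric(d)) - p), 4 * se + 1e-9)
  }
  expect_equal(sort(unique(null)), sort(unique(c(-log(3), 1:4))),
               tolerance = 1e-12)
})

test_that("z and empirical p follow their defining identities", {
  r <- z_and_p(1, c(1, 2, 3))
  expect_equal(r$z, (1 - 2) / 1)
  expect_equal(r$p_emp, 2 / 4)
  null <- rnorm(999, 5)
  r2 <- z_and_p(-10, null)
  expect_equal(r2$p_emp, 1 / 1000)
  expect_equal(r2$z, (-10 - mean(null)) / sd(null), tolerance = 1e-12)
  r3 <- z_and_p(1, rep(2, 10))
  expect_true(is.na(r3$z))
  expect_equal(r3$p_emp, 1 / 11)
  expect_error(z_and_p(1, numeric()), "empty")
})

test_that("drug screening applies strict gates and orders by z", {
  res <- data.frame(drug = c("a", "b", "c", "d"),
                    d_obs = c(1.1, 1.2, 0.3, 0.5),
                    z = c(-3, -6, -1, -5),
                    fdr = c(0.01, 1e-6, 0.2, 0.01),
                    evaluable = TRUE)
  expect_identical(screen_drugs(res), c("d", "a"))
})

test_that("planted proximal drugs get negative z in the top decile", {
  hit <- 0; tot <- 0
  for (s in 1:20) {
    sp <- synth_ppi(150, c(8, 6, 5), 0.02, seed = s)
    g <- build_graph(sp$edges)
    S <- intersect(sp$truth$modules[[1]], igraph::V(g)$name)
    dt <- synth_drug_targets(sp$edges, S, n_proximal = 3, n_random = 27,
                             targets_per_drug = 4, seed = s)
    pr <- run_proximity(g, S, dt$drugs, n_perm = 500, seed = s)
    zr <- rank(pr$z)
    dec <- ceiling(nrow(pr) / 10)
    for (d in dt$truth$proximal_drugs) {
      tot <- tot + 1
      i <- which(pr$drug == d)
      hit <- hit + (pr$z[i] < 0 && zr[i] <= dec)
    }
  }
  expect_gte(hit / tot, 0.9)
})
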