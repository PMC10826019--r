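test_that("expression generator honours shape, determinism and contracts", {
  r <- synth_expression(100, 4, 4, 10, 2, 0.5, seed = 1)
  expect_equal(dim(r$expr$values), c(100, 8))
  expect_equal(nrow(r$truth$de_genes), 10)
  expect_setequal(r$truth$de_genes$log2fc, c(2, -2))
  r2 <- synth_expression(100, 4, 4, 10, 2, 0.5, seed = 1)
  expect_identical(r$expr$values, r2$expr$values)
  r3 <- synth_expression(100, 4, 4, 10, 2, 0.5, seed = 2)
  expect_false(identical(r$expr$values, r3$expr$values))

  expect_equal(nrow(synth_expression(50, 4, 4, 10, 0, 0.5,
                                     seed = 1)$truth$de_genes), 0)
  expect_error(synth_expression(5, 4, 4, 10, 2, 0.5, seed = 1), "n_de")
  expect_error(synth_expression(50, 1, 4, 5, 2, 0.5, seed = 1), "samples")
})

test_that("planted log2 fold-changes are calibrated on average", {
  # Mean estimated |log2FC| of planted genes across replicates should sit
  # within 10% of the requested effect.
  est <- replicate(200, {
    r <- synth_expression(60, 4, 4, 10, 2, 0.5, seed = sample.int(1e6, 1))
    fit <- fit_moderated_t(r$expr)
    idx <- match(r$truth$de_genes$gene, fit$table$gene)
    mean(fit$table$log2fc[idx] * sign(r$truth$de_genes$log2fc))
  })
  expect_lt(abs(mean(est) - 2), 0.2)
})

test_that("PPI generator plants cliques, hub wiring and is deterministic", {
  r <- synth_ppi(50, c(6, 5, 4), 0.02, seed = 7)
  key <- paste(pmin(r$edges$gene_a, r$edges$gene_b),
               pmax(r$edges$gene_a, r$edges$gene_b))
  for (m in r$truth$modules) {
    pr <- t(utils::combn(sort(m), 2))
    expect_true(all(paste(pr[, 1], pr[, 2]) %in% key))
  }
  expect_true(r$truth$hub_gene %in% r$truth$modules[[1]])
  expect_identical(r$edges,
                   synth_ppi(50, c(6, 5, 4), 0.02, seed = 7)$edges)

  # One 4-module, no background, no extra spokes: exactly the 6 clique edges.
  r1 <- synth_ppi(4, 4, 0, seed = 1, hub_extra = 0)
  expect_equal(nrow(r1$edges), 6)
  expect_error(synth_ppi(10, c(4, 2), 0, seed = 1), ">= 3")
  expect_error(synth_ppi(5, c(4, 4), 0, seed = 1), "exceed")
})

test_that("drug generator separates proximal and random drugs", {
  sp <- synth_ppi(60, c(6, 5), 0.02, seed = 3)
  S <- sp$truth$modules[[1]]
  r <- synth_drug_targets(sp$edges, S, n_proximal = 3, n_random = 20,
                          targets_per_drug = 3, seed = 5)
  expect_length(r$drugs, 23)
  expect_length(r$truth$proximal_drugs, 3)
  nodes <- unique(c(sp$edges$gene_a, sp$edges$gene_b))
  nbr <- unique(c(sp$edges$gene_b[sp$edges$gene_a %in% S],
                  sp$edges$gene_a[sp$edges$gene_b %in% S]))
  for (d in r$truth$proximal_drugs)
    expect_true(all(r$drugs[[d]] %in% union(S, nbr)))
  r2 <- synth_drug_targets(sp$edges, S, n_proximal = 3, n_random = 20,
                           targets_per_drug = 3, seed = 5)
  expect_identical(unclass(r$drugs), unclass(r2$drugs))
  expect_error(synth_drug_targets(sp$edges, "ABSENT", 1, 1, 2, seed = 1),
               "non-empty")

  # All-inside-S targets force a non-positive weighted distance.
  g <- build_graph(sp$edges)
  Sg <- intersect(S, igraph::V(g)$name)
  wd <- weighted_distance(g, Sg, Sg[1:3])
  expect_lte(wd$d, 0)
})

test_that("signature generator couples members to the hub as requested", {
  base <- synth_expression(400, 4, 4, 0, 0, 0.5, seed = 2)
  hub <- rownames(base$expr$values)[1]
  r <- synth_signatures(base$expr, hub, n_signatures = 28,
                        genes_per_sig = 5, coupling = -1, seed = 4)
  expect_length(r$signatures$sets, 28)
  sc <- ssgsea_scores(r$expr, r$signatures)
  h <- r$expr$values[hub, ]
  # Member ranks are perfectly reversed, but the positions of the other
  # (noisy) genes still jitter the running sum: near-perfect, not exact.
  for (i in seq_len(nrow(sc)))
    expect_lte(stats::cor(h, sc[i, ], method = "spearman"), -0.85)
  expect_lte(stats::cor(h, immune_score(sc), method = "spearman"), -0.95)

  # coupling = 0: mean correlation near zero across seeds.
  rhos <- vapply(1:50, function(s) {
    r0 <- synth_signatures(base$expr, hub, n_signatures = 2,
                           genes_per_sig = 5, coupling = 0, seed = s)
    sc0 <- ssgsea_scores(r0$expr, r0$signatures)
    mean(apply(sc0, 1, function(v)
      stats::cor(r0$expr$values[hub, ], v, method = "spearman")))
  }, 0)
  expect_lt(abs(mean(rhos)), 0.2)

  expect_error(synth_signatures(base$expr, "NOPE", 2, 5, -0.5, seed = 1),
               "hub")
})
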