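test_that("ssGSEA matches the hand-evaluated running sum", {
  # 3 genes, signature = the top-ranked gene, alpha = 0:
  # ES = (1-0) + (1-1/2) + (1-1) = 1.5
  v <- matrix(c(3, 2, 1), 3, 1, dimnames = list(c("A", "B", "C"), "s1"))
  v <- cbind(v, v); colnames(v) <- c("u1", "s1")
  expr <- expression_matrix(v, c(u1 = "unstable", s1 = "stable"))
  sc <- ssgsea_scores(expr, gene_set_collection(list(top = "A")), alpha = 0)
  expect_equal(unname(sc["top", ]), c(1.5, 1.5))

  expect_error(ssgsea_scores(expr,
                             gene_set_collection(list(all = c("A", "B", "C")))),
               "all measured")
  expect_error(ssgsea_scores(expr, gene_set_collection(list(none = "ZZ"))),
               "no measured")
})

test_that("ssGSEA is invariant under monotone transforms of a sample", {
  r <- synth_expression(200, 4, 4, 0, 0, 0.5, seed = 6)
  sets <- gene_set_collection(list(
    a = rownames(r$expr$values)[1:15],
    b = rownames(r$expr$values)[30:60]))
  s1 <- ssgsea_scores(r$expr, sets)
  v <- r$expr$values
  v[, 1] <- exp(v[, 1] / 2)          # strictly monotone
  v[, 5] <- rank(v[, 5]) * 10
  expr2 <- expression_matrix(v, r$expr$groups)
  s2 <- ssgsea_scores(expr2, sets)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("a perfectly anti-coupled member gives exactly reversed scores", {
  # Hub rises 1..8; the single member falls 8..1 across a fixed fine grid
  # of background genes, so its rank — and hence the score — is a strictly
  # decreasing function of the hub and the Spearman correlation is -1.
  n_bg <- 50
  v <- rbind(HUB = 1:8, MEM = 8:1,
             matrix(rep(seq(0.5, 8.5, length.out = n_bg), 8), n_bg, 8))
  rownames(v)[-(1:2)] <- sprintf("B%02d", seq_len(n_bg))
  colnames(v) <- sprintf("s%d", 1:8)
  expr <- expression_matrix(v, setNames(rep(c("unstable", "stable"), 4),
                                        colnames(v)))
  sc <- ssgsea_scores(expr, gene_set_collection(list(sig = "MEM")))
  expect_equal(cor(v["HUB", ], sc["sig", ], method = "spearman"), -1)
  expect_equal(cor(v["HUB", ], immune_score(sc), method = "spearman"), -1)
})

test_that("the immune score is the per-sample sum of signature scores", {
  r <- synth_expression(100, 4, 4, 0, 0, 0.5, seed = 7)
  sets <- gene_set_collection(list(a = rownames(r$expr$values)[1:5],
                                   b = rownames(r$expr$values)[6:12]))
  sc <- ssgsea_scores(r$expr, sets)
  expect_equal(immune_score(sc), colSums(sc))
  expect_equal(immune_score(sc * 2), 2 * immune_score(sc))
})

test_that("exact Spearman p agrees with full enumeration", {
  # The n = 8 reference arrangement: sum of squared rank differences 158.
  y <- c(7, 8, 4, 5, 6, 3, 2, 1)
  expect_equal(sum((1:8 - y)^2), 158)
  r <- spearman_exact(1:8, y)
  expect_equal(r$rho, -0.8809524, tolerance = 1e-6)
  expect_equal(round(r$p, 4), 0.0072)
  expect_identical(r$method, "spearman_exact")

  expect_equal(spearman_exact(1:4, 4:1)$p, 2 / 24, tolerance = 1e-12)
  expect_equal(spearman_exact(1:3, 1:3)$p, 2 / 6, tolerance = 1e-12)

  # Exhaustive independent enumeration for several n <= 7 vectors.
  set.seed(41)
  for (n in c(5, 6, 7)) {
    x <- sample(100, n); y2 <- sample(100, n)
    r2 <- spearman_exact(x, y2)
    expect_equal(r2$p, oracle_spearman_p(x, y2), tolerance = 1e-12)
  }
  expect_error(spearman_exact(rep(1, 4), 1:4), "constant")
})

test_that("tied or large inputs fall back to the flagged t-approximation", {
  r <- spearman_exact(c(1, 1, 2, 3, 4), c(2, 1, 3, 4, 5))
  expect_identical(r$method, "spearman_approx")
  r2 <- spearman_exact(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  expect_identical(r2$method, "spearman_approx")
})

test_that("Pearson test matches the closed-form t reference", {
  set.seed(43)
  x <- rnorm(8)
  y <- 0.9 * scale(x)[, 1] + sqrt(1 - 0.81) * scale(rnorm(8))[, 1]
  r <- pearson_corr_test(x, y)
  ref <- cor.test(x, y)
  expect_equal(r$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)

  # r = 0.9 at n = 8: t = 5.058, p = 0.0023.
  t9 <- 0.9 * sqrt(6 / (1 - 0.81))
  expect_equal(t9, 5.0576, tolerance = 1e-3)
  expect_lt(abs(2 * pt(-t9, 6) - 0.0023), 1e-4)

  d <- pearson_corr_test(1:5, 2 * (1:5) + 3)
  expect_true(d$degenerate)
  expect_equal(d$p, 0)
  expect_error(pearson_corr_test(rep(1, 5), 1:5), "constant")
})

test_that("anchor-related genes obey strict signed thresholds", {
  set.seed(47)
  n <- 8
  anchor <- rnorm(n)
  mk <- function(r) r * scale(anchor)[, 1] +
    sqrt(max(0, 1 - r^2)) * scale(rnorm(n))[, 1]
  v <- rbind(anchor = anchor, pos = mk(0.99), neg = -mk(0.99),
             noise = rnorm(n), exact = anchor * 2)
  rownames(v) <- c("ANCHOR", "POS", "NEG", "NOISE", "EXACT")
  colnames(v) <- sprintf("s%d", 1:n)
  expr <- expression_matrix(v, setNames(rep(c("unstable", "stable"), 4),
                                        colnames(v)))
  rel <- related_gene_set(expr, "ANCHOR")
  expect_true("POS" %in% rel)
  expect_true("EXACT" %in% rel)
  expect_false("NEG" %in% rel)
  expect_false("NOISE" %in% rel)
  rel_abs <- related_gene_set(expr, "ANCHOR", absolute = TRUE)
  expect_true("NEG" %in% rel_abs)
  expect_error(related_gene_set(expr, "MISSING"), "not measured")
})

test_that("hub-coupled signatures yield negative immune correlations", {
  neg <- vapply(1:100, function(s) {
    base <- synth_expression(150, 4, 4, 0, 0, 0.5, seed = s)
    hub <- rownames(base$expr$values)[1]
    r <- synth_signatures(base$expr, hub, n_signatures = 5,
                          genes_per_sig = 6, coupling = -0.9, seed = s)
    sc <- ssgsea_scores(r$expr, r$signatures)
    cor(r$expr$values[hub, ], immune_score(sc), method = "spearman") < 0
  }, TRUE)
  expect_gte(mean(neg), 0.95)
})
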