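# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain adjacency matrices, breadth-first searches
# and explicit enumeration, so that agreement is evidence rather than
# tautology.

# Random Erdos-Renyi edge table (confidence 900 throughout).
rand_graph_edges <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(nrow(pairs), 2)] <- TRUE
  edge_table(pairs[keep, 1], pairs[keep, 2], rep(900, sum(keep)))
}

# Adjacency matrix over the node set of an edge table.
adj_matrix <- function(edges) {
  ids <- sort(unique(c(edges$gene_a, edges$gene_b)))
  A <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(edges))) {
    A[edges$gene_a[i], edges$gene_b[i]] <- TRUE
    A[edges$gene_b[i], edges$gene_a[i]] <- TRUE
  }
  diag(A) <- FALSE
  A
}

# BFS hop distances and geodesic counts from one source.
bfs_sigma <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n); sigma <- rep(0, n)
  d[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      for (w in which(A[v, ])) {
        if (is.infinite(d[w])) { d[w] <- d[v] + 1; nxt <- c(nxt, w) }
        if (d[w] == d[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(d = d, sigma = sigma)
}

# Degree / betweenness / closeness by explicit shortest-path counting,
# normalized within connected components.
oracle_centralities <- function(edges) {
  A <- adj_matrix(edges)
  ids <- rownames(A)
  n <- nrow(A)
  bf <- lapply(seq_len(n), function(s) bfs_sigma(A, s))
  D <- do.call(rbind, lapply(bf, `[[`, "d"))
  SG <- do.call(rbind, lapply(bf, `[[`, "sigma"))
  comp <- rep(NA_integer_, n); cid <- 0
  for (v in seq_len(n)) if (is.na(comp[v])) {
    cid <- cid + 1
    comp[is.finite(D[v, ])] <- cid
  }
  btw <- rep(0, n); clo <- rep(0, n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (is.infinite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t])
        btw[v] <- btw[v] + SG[s, v] * SG[v, t] / SG[s, t]
    }
    nc <- sum(comp == comp[v])
    if (nc > 2) btw[v] <- btw[v] / ((nc - 1) * (nc - 2) / 2)
    else btw[v] <- 0
    if (nc > 1) clo[v] <- (nc - 1) / sum(D[v, comp == comp[v]])
  }
  data.frame(node = ids, degree = rowSums(A), betweenness = btw,
             closeness = clo, stringsAsFactors = FALSE)
}

# Step-up BH from its definition: q_(i) = min_{j >= i} m p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(i)
    min(1, min(m * p[o][i:m] / (i:m))), 0)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Hypergeometric upper tail by explicit summation of the pmf.
oracle_hyper_tail <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Literal evaluation of the weighted-distance formula:
# d(S,T) = (1/|T|) sum_t min_s [ d(s,t) + omega_t ], omega_t = -ln(deg+1)
# if t is in S else 0; unreachable targets dropped.
oracle_weighted_distance <- function(edges, S, targets) {
  A <- adj_matrix(edges)
  ids <- rownames(A)
  S <- intersect(S, ids)
  targets <- intersect(unique(targets), ids)
  deg <- rowSums(A)
  terms <- c()
  for (t in targets) {
    omega <- if (t %in% S) -log(deg[[t]] + 1) else 0
    best <- Inf
    for (s in S) {
      d <- bfs_sigma(A, match(s, ids))$d[match(t, ids)]
      best <- min(best, d + omega)
    }
    if (is.finite(best)) terms <- c(terms, best)
  }
  if (length(terms) == 0) return(list(d = NA_real_, n_used = 0L))
  list(d = mean(terms), n_used = length(terms))
}

# Exact two-sided Spearman permutation p by recursive enumeration, using
# stats::cor rather than the sum-of-squared-differences identity.
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  rho_obs <- stats::cor(x, y, method = "spearman")
  count <- 0; total <- 0
  recurse <- function(remaining, chosen) {
    if (!length(remaining)) {
      total <<- total + 1
      if (abs(stats::cor(x, y[chosen], method = "spearman")) >=
          abs(rho_obs) - 1e-12)
        count <<- count + 1
      return(invisible())
    }
    for (i in seq_along(remaining))
      recurse(remaining[-i], c(chosen, remaining[i]))
  }
  recurse(seq_len(n), integer())
  count / total
}

# Small two-group expression fixture built in code.
tiny_expr <- function(values, n_case = 2, n_control = 2) {
  genes <- sprintf("G%d", seq_len(nrow(values)))
  samples <- c(sprintf("u%d", seq_len(n_case)),
               sprintf("s%d", seq_len(n_control)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values,
                    setNames(rep(c("unstable", "stable"),
                                 c(n_case, n_control)), samples))
}
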