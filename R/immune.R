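# Single-sample gene-set enrichment (rank-weighted running-sum scores), an
# aggregate immune score, and small-sample correlation tests. Exact Spearman
# p-values are obtained by full enumeration of rank permutations when the
# sample size permits (n <= 9, no ties), which covers the 8-sample designs
# this pipeline targets.

#' ssGSEA enrichment scores
#'
#' Per sample, genes are ranked by expression in descending order (the top
#' gene has rank N) and, walking down the ranking, the score accumulates
#' the difference between the weighted in-signature cumulative proportion
#' and the unweighted out-of-signature cumulative proportion:
#' \deqn{ES = \sum_{i=1}^{N} [P_{in}^w(i) - P_{out}(i)],}
#' where the in-signature weight of the gene at position `i` is
#' `rank^alpha`. Raw (un-normalized) scores are returned by default;
#' `normalize = TRUE` divides every score by `max - min` over the whole
#' result.
#'
#' @param expr An [expression_matrix()].
#' @param sigs A [gene_set_collection()]; every signature must overlap the
#'   measured genes and be a proper subset of them.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @param normalize Apply global (max - min) normalization (default FALSE).
#' @return Numeric matrix, signatures x samples, of class `SsgseaScores`
#'   with attributes `alpha` and `normalized`.
#' @export
ssgsea_scores <- function(expr, sigs, alpha = 0.25, normalize = FALSE) {
  v <- expr$values
  N <- nrow(v)
  genes <- rownames(v)
  memb <- lapply(names(sigs$sets), function(nm) {
    m <- intersect(sigs$sets[[nm]], genes)
    if (length(m) == 0)
      stop("signature '", nm, "' has no measured genes")
    if (length(m) == N)
      stop("signature '", nm, "' covers all measured genes")
    m
  })
  names(memb) <- names(sigs$sets)
  out <- matrix(NA_real_, length(memb), ncol(v),
                dimnames = list(names(memb), colnames(v)))
  for (s in seq_len(ncol(v))) {
    ord <- order(-v[, s], seq_len(N))        # descending; stable tie-break
    ranked_genes <- genes[ord]
    rk <- N:1                                # rank N = highest expression
    wts <- rk^alpha
    for (gi in seq_along(memb)) {
      inset <- ranked_genes %in% memb[[gi]]
      p_in <- cumsum(wts * inset) / sum(wts[inset])
      p_out <- cumsum(!inset) / (N - sum(inset))
      out[gi, s] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- max(out) - min(out)
    if (rng > 0) out <- out / rng
  }
  structure(out, alpha = alpha, normalized = normalize,
            class = c("SsgseaScores", "matrix", "array"))
}

#' Aggregate immune score
#'
#' Per-sample sum of the signature enrichment scores — a simple aggregate
#' over an immune signature panel (linear in every signature's score).
#'
#' @param scores A matrix from [ssgsea_scores()].
#' @return Named numeric vector, one value per sample.
#' @export
immune_score <- function(scores) {
  if (nrow(scores) < 1) stop("need >= 1 signature")
  colSums(scores)
}

# All permutations of 1..n as an (n!) x n integer matrix, in a fixed order.
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- perm_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    q <- p + (p >= i)
    cbind(rep(i, nrow(q)), q)
  }))
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' The coefficient is computed on midranks via
#' \eqn{\rho = 1 - 6\sum d^2 / (n(n^2-1))}. When `n <= 9` and there are no
#' ties, the two-sided p-value is exact: all `n!` rank permutations are
#' enumerated and `p` is the proportion with
#' \eqn{|\rho_{perm}| \ge |\rho_{obs}| - 10^{-12}}. Otherwise the
#' t-approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} is used and the
#' result is flagged via `method`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return List of class `CorrelationResult` with `rho`, `p`, `n`, `method`
#'   (`"spearman_exact"` or `"spearman_approx"`).
#' @export
spearman_exact <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal lengths n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  denom <- n * (n^2 - 1)
  rho <- 1 - 6 * sum((rx - ry)^2) / denom
  no_ties <- !anyDuplicated(rx) && !anyDuplicated(ry)
  if (n <= 9 && no_ties) {
    perms <- perm_matrix(n)
    d2 <- rowSums((matrix(rx, nrow(perms), n, byrow = TRUE) - perms)^2)
    rho_all <- 1 - 6 * d2 / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "spearman_exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
    }
    method <- "spearman_approx"
  }
  structure(list(rho = rho, p = p, n = n, method = method),
            class = "CorrelationResult")
}

#' Pearson correlation with t-test p-value
#'
#' Product-moment correlation with the two-sided p from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on `n - 2` degrees of freedom. Exactly
#' collinear data give `r = +/-1`, `p = 0`, flagged `degenerate`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return List of class `CorrelationResult` with `r`, `p`, `n`, `method`,
#'   `degenerate`.
#' @export
pearson_corr_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal lengths n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  r <- stats::cor(x, y)
  degenerate <- abs(r) >= 1 - 1e-12
  p <- if (degenerate) 0 else
    2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
  structure(list(r = r, p = p, n = n, method = "pearson",
                 degenerate = degenerate),
            class = "CorrelationResult")
}

#' Genes highly correlated with an anchor gene
#'
#' Returns all measured genes (other than the anchor) whose Pearson
#' correlation with the anchor exceeds `r_min` (strict, signed: positive
#' correlation only unless `absolute = TRUE`) at `p < p_max` (strict).
#' Constant genes are skipped.
#'
#' @param expr An [expression_matrix()].
#' @param anchor Anchor gene id (must be measured, non-constant).
#' @param r_min Correlation threshold (default 0.9).
#' @param p_max P-value ceiling (default 0.001).
#' @param absolute Use `|r|` instead of signed `r` (default FALSE).
#' @return Character vector of gene ids.
#' @export
related_gene_set <- function(expr, anchor, r_min = 0.9, p_max = 0.001,
                             absolute = FALSE) {
  v <- expr$values
  if (!(anchor %in% rownames(v))) stop("anchor gene not measured")
  a <- v[anchor, ]
  if (stats::sd(a) == 0) stop("anchor gene is constant")
  others <- setdiff(rownames(v), anchor)
  sds <- apply(v[others, , drop = FALSE], 1, stats::sd)
  others <- others[sds > 0]
  r <- as.numeric(stats::cor(a, t(v[others, , drop = FALSE])))
  n <- length(a)
  r_clip <- pmin(1 - 1e-15, pmax(-1 + 1e-15, r))
  p <- 2 * stats::pt(-abs(r_clip * sqrt((n - 2) / (1 - r_clip^2))),
                     df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  eff <- if (absolute) abs(r) else r
  others[eff > r_min & p < p_max]
}
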