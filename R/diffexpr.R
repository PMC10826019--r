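# Differential expression: empirical-Bayes moderated t-statistics with
# gene-wise variances shrunk toward a common prior, Benjamini-Hochberg
# control, and threshold screening. Inputs are assumed to be normalized,
# log2-scale values; log2 fold-changes are differences of group means (no
# re-logging), with orientation case (unstable) minus control (stable).

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)). Returns NA on divergence.
trigamma_inverse <- function(y, tol = 1e-10, max_iter = 60) {
  if (y <= 0) return(NA_real_)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in seq_len(max_iter)) {
    f <- trigamma(x) - y
    if (abs(f) < tol * y) return(x)
    step <- f / psigamma(x, 2)
    x <- x - step
    if (!is.finite(x) || x <= 0) return(NA_real_)
  }
  NA_real_
}

#' Moderated t-test for two-group expression data
#'
#' Fits the standard empirical-Bayes variance model: gene-wise pooled
#' variances \eqn{s_g^2} (on \eqn{d_g} degrees of freedom) are shrunk toward
#' a prior \eqn{s_0^2} with prior degrees of freedom \eqn{d_0},
#' \deqn{s_{post,g}^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g),}
#' and the moderated statistic
#' \eqn{t_g = \Delta\bar{x}_g / (s_{post,g}\sqrt{1/n_1 + 1/n_2})} is referred
#' to a t distribution on \eqn{d_0 + d_g} degrees of freedom (two-sided).
#' The hyperparameters are estimated by moment matching on the log sample
#' variances (trigamma inversion by Newton iteration). With fewer than 10
#' genes, or if the inversion diverges, the fit falls back to the ordinary
#' pooled-variance t (\eqn{d_0 = 0}); the fallback is recorded in `params`.
#'
#' Genes with zero variance in both groups and zero mean difference get
#' \eqn{t = 0}, \eqn{p = 1} and are flagged.
#'
#' @param expr An [expression_matrix()] with >= 2 samples per group.
#' @return List with `table` (data.frame: `gene`, `log2fc`, `t`, `p`, `fdr`,
#'   `direction`, `flagged`) and `params` (list: `d0`, `s0_sq`, `fallback`).
#' @export
fit_moderated_t <- function(expr) {
  ca <- expr$values[, case_samples(expr), drop = FALSE]
  co <- expr$values[, control_samples(expr), drop = FALSE]
  n1 <- ncol(ca); n2 <- ncol(co)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples")
  ng <- nrow(expr$values)
  if (ng < 1) stop("need >= 1 gene")
  m1 <- rowMeans(ca); m2 <- rowMeans(co)
  lfc <- m1 - m2
  dg <- n1 + n2 - 2
  v1 <- apply(ca, 1, stats::var)
  v2 <- apply(co, 1, stats::var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg

  d0 <- 0; s0_sq <- NA_real_; fallback <- TRUE
  pos <- s2 > 0
  if (ng >= 10 && sum(pos) >= 10) {
    e <- log(s2[pos]) - digamma(dg / 2) + log(dg / 2)
    evar <- stats::var(e)
    target <- evar - trigamma(dg / 2)
    if (is.finite(target) && target > 0) {
      half_d0 <- trigamma_inverse(target)
      if (!is.na(half_d0)) {
        d0 <- 2 * half_d0
        s0_sq <- exp(mean(e) + digamma(half_d0) - log(half_d0))
        fallback <- FALSE
      }
    } else if (is.finite(target)) {
      d0 <- Inf
      s0_sq <- exp(mean(e))
      fallback <- FALSE
    }
  }
  if (fallback) {
    s2_post <- s2
    df_tot <- dg
  } else if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, ng)
    df_tot <- Inf
  } else {
    s2_post <- (d0 * s0_sq + dg * s2) / (d0 + dg)
    df_tot <- d0 + dg
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, Inf * sign(lfc)))
  p <- ifelse(is.finite(t_stat), 2 * stats::pt(-abs(t_stat), df = df_tot), 0)
  flagged <- se == 0
  p[flagged & lfc == 0] <- 1
  tab <- data.frame(
    gene = rownames(expr$values),
    log2fc = lfc,
    t = t_stat,
    p = p,
    fdr = bh_adjust(p),
    direction = ifelse(lfc >= 0, "up", "down"),
    flagged = flagged,
    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab,
       params = list(d0 = d0, s0_sq = s0_sq, fallback = fallback))
}

#' Screen differentially expressed genes
#'
#' Keeps genes with `|log2FC| > lfc_min` and `fdr < fdr_max`; both
#' inequalities are strict.
#'
#' @param table DEG table from [fit_moderated_t()].
#' @param lfc_min Minimum absolute log2 fold-change (default 1).
#' @param fdr_max FDR ceiling (default 0.05).
#' @return Character vector of gene ids, in table order.
#' @export
screen_degs <- function(table, lfc_min = 1, fdr_max = 0.05) {
  if (lfc_min <= 0 || fdr_max <= 0) stop("thresholds must be positive")
  table$gene[abs(table$log2fc) > lfc_min & table$fdr < fdr_max]
}
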