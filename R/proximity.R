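# Weighted network proximity between drug target sets and a disease gene
# set, with a permutation null. The observed statistic is
#
#   d(S, T) = (1/|T'|) * sum over t in T' of [ min_{s in S} d(s, t) + w_t ]
#
# where d(s, t) is the unweighted hop distance, w_t = -ln(degree(t) + 1) if
# the target t belongs to the disease set S, and w_t = 0 otherwise. Because
# w_t does not depend on s, taking the minimum before or after adding the
# weight yields the same value. Targets off the network or unreachable from
# every disease gene are dropped from the average (and counted) rather than
# assigned an infinite penalty. The null rescores uniformly drawn node sets
# of the same size; z = (d_obs - mu_null) / sigma_null and the empirical p
# uses the add-one estimator, so p is never exactly zero.

# Per-node minimum hop distance to S, and the self-target weight omega.
proximity_profile <- function(g, S) {
  nodes <- igraph::V(g)$name
  S <- intersect(S, nodes)
  if (length(S) == 0) stop("disease set S is empty after network restriction")
  dm <- igraph::distances(g, v = S, to = igraph::V(g), weights = NA)
  dmin <- apply(dm, 2, min)
  names(dmin) <- nodes
  omega <- setNames(numeric(length(nodes)), nodes)
  deg <- igraph::degree(g)
  omega[S] <- -log(deg[S] + 1)
  list(S = S, dmin = dmin, omega = omega)
}

profile_distance <- function(profile, targets) {
  reach <- targets[is.finite(profile$dmin[targets])]
  if (length(reach) == 0)
    return(list(d = NA_real_, n_used = 0L))
  list(d = mean(profile$dmin[reach] + profile$omega[reach]),
       n_used = length(reach))
}

#' Weighted distance from a drug target set to a disease gene set
#'
#' @param g A [build_graph()] network.
#' @param S Character vector of disease genes (restricted to network
#'   nodes; must be non-empty after restriction).
#' @param targets Character vector of drug target genes; off-network and
#'   unreachable targets are dropped from the average and counted.
#' @return List with `d` (the weighted distance; `NA` if no usable target),
#'   `n_used` (targets contributing), `n_off_network`.
#' @export
weighted_distance <- function(g, S, targets) {
  nodes <- igraph::V(g)$name
  on_net <- intersect(unique(targets), nodes)
  prof <- proximity_profile(g, S)
  res <- profile_distance(prof, on_net)
  res$n_off_network <- length(unique(targets)) - length(on_net)
  res
}

#' Permutation null distribution of the weighted distance
#'
#' Draws `n_perm` uniform samples of `target_size` nodes (without
#' replacement) from the network and scores each with the weighted
#' distance to `S`. Draws in which every node is unreachable from `S` are
#' redrawn (at most 100 retries each, then an error). Deterministic given
#' the seed.
#'
#' @param g A [build_graph()] network.
#' @param S Disease gene set.
#' @param target_size Nodes per draw (`<=` node count).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of length `n_perm`.
#' @export
null_distribution <- function(g, S, target_size, n_perm = 10000, seed = 1) {
  nodes <- igraph::V(g)$name
  if (target_size > length(nodes))
    stop("target_size exceeds the node count")
  if (n_perm < 1) stop("n_perm must be >= 1")
  prof <- proximity_profile(g, S)
  set.seed(derive_seed(seed, "proximity_null"))
  out <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    d <- NA_real_
    for (try in 1:100) {
      R <- sample(nodes, target_size)
      d <- profile_distance(prof, R)$d
      if (!is.na(d)) break
    }
    if (is.na(d)) stop("could not draw a reachable null target set")
    out[i] <- d
  }
  out
}

#' Standardized score and empirical p against a permutation null
#'
#' `z = (d_obs - mean(null)) / sd(null)` (sample standard deviation,
#' `n - 1` denominator; `z` is `NA` when the null is degenerate) and
#' `p = (1 + #\{null <= d_obs\}) / (1 + length(null))`, one-sided: a small
#' distance means the targets are proximal to the disease set.
#'
#' @param d_obs Observed weighted distance.
#' @param null Numeric vector from [null_distribution()] (non-empty).
#' @return List with `z`, `p_emp`, `mu`, `sigma`.
#' @export
z_and_p <- function(d_obs, null) {
  if (length(null) == 0) stop("empty null distribution")
  mu <- mean(null)
  sigma <- stats::sd(null)
  z <- if (length(null) > 1 && sigma > 0) (d_obs - mu) / sigma else NA_real_
  p <- (1 + sum(null <= d_obs)) / (1 + length(null))
  list(z = z, p_emp = p, mu = mu, sigma = if (is.na(sigma)) 0 else sigma)
}

#' Score every drug's proximity to a disease gene set
#'
#' Computes the observed weighted distance per drug, a shared permutation
#' null per distinct on-network target-set size, the standardized score and
#' add-one empirical p, BH-adjusted FDR across evaluable drugs, and the
#' screening verdict (`d_obs < d_max` and `fdr < fdr_max`, both strict).
#'
#' @param g A [build_graph()] network.
#' @param S Disease gene set.
#' @param drugs A [drug_target_map()].
#' @param n_perm Permutations per null (default 10000).
#' @param seed Integer seed.
#' @param d_max Distance screening threshold (default 1.2).
#' @param fdr_max FDR gate (default 0.05).
#' @return data.frame with one row per drug: `drug`, `d_obs`,
#'   `n_targets`, `n_used`, `mu`, `sigma`, `z`, `p_emp`, `fdr`,
#'   `evaluable`, `screened`.
#' @export
run_proximity <- function(g, S, drugs, n_perm = 10000, seed = 1,
                          d_max = 1.2, fdr_max = 0.05) {
  nodes <- igraph::V(g)$name
  prof <- proximity_profile(g, S)
  on_net <- lapply(drugs, function(t) intersect(unique(t), nodes))
  sizes <- lengths(on_net)
  nulls <- list()
  for (sz in sort(unique(sizes[sizes > 0]))) {
    nulls[[as.character(sz)]] <-
      null_distribution(g, S, sz, n_perm = n_perm,
                        seed = derive_seed(seed, paste0("size", sz)))
  }
  rows <- lapply(names(drugs), function(dr) {
    tn <- on_net[[dr]]
    res <- profile_distance(prof, tn)
    if (res$n_used == 0)
      return(data.frame(drug = dr, d_obs = NA_real_,
                        n_targets = length(drugs[[dr]]), n_used = 0L,
                        mu = NA_real_, sigma = NA_real_, z = NA_real_,
                        p_emp = NA_real_, evaluable = FALSE,
                        stringsAsFactors = FALSE))
    zp <- z_and_p(res$d, nulls[[as.character(length(tn))]])
    data.frame(drug = dr, d_obs = res$d,
               n_targets = length(drugs[[dr]]), n_used = res$n_used,
               mu = zp$mu, sigma = zp$sigma, z = zp$z, p_emp = zp$p_emp,
               evaluable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  ev <- out$evaluable
  out$fdr[ev] <- bh_adjust(out$p_emp[ev])
  out$screened <- ev & !is.na(out$d_obs) &
    out$d_obs < d_max & out$fdr < fdr_max
  rownames(out) <- NULL
  out
}

#' Screened drug candidates
#'
#' @param results Result table from [run_proximity()].
#' @param d_max,fdr_max Screening thresholds (both strict; defaults 1.2
#'   and 0.05).
#' @return Character vector of drug ids ordered by ascending `z`.
#' @export
screen_drugs <- function(results, d_max = 1.2, fdr_max = 0.05) {
  keep <- results$evaluable & results$d_obs < d_max & results$fdr < fdr_max
  keep[is.na(keep)] <- FALSE
  res <- results[keep, , drop = FALSE]
  res$drug[order(res$z)]
}

#' Binned density of observed vs null distances
#'
#' Summarizes the screened landscape: histogram densities of the observed
#' per-drug distances and of a pooled sample of the null draws on a common
#' set of bins.
#'
#' @param results Result table from [run_proximity()].
#' @param null Numeric vector of null distances (e.g. from
#'   [null_distribution()]).
#' @param n_bins Number of bins (default 30).
#' @return data.frame with `bin_mid`, `density_observed`, `density_null`.
#' @export
proximity_density <- function(results, null, n_bins = 30) {
  obs <- results$d_obs[results$evaluable]
  rng <- range(c(obs, null), finite = TRUE)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h_obs <- graphics::hist(obs, breaks = brk, plot = FALSE)
  h_nul <- graphics::hist(null, breaks = brk, plot = FALSE)
  data.frame(bin_mid = h_obs$mids,
             density_observed = h_obs$density,
             density_null = h_nul$density)
}
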