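# Seeded synthetic-data generators. Each generator is a pure function of its
# arguments (including the seed) and returns the generated object together
# with a ground-truth record, so that recovery tests can score the pipeline
# against known planted structure. Gaussian noise on the log2 scale matches
# the moderated-t model assumptions of the differential-expression stage.

#' Simulate a two-group expression matrix with planted fold-changes
#'
#' Baseline expression is i.i.d. normal per gene around a gene-specific mean;
#' `n_de` planted genes are shifted by +/- `effect` log2 units in the case
#' group (half up, half down). The default group sizes mirror the small
#' plaque cohorts this pipeline is designed around (4 vs 4).
#'
#' @param n_genes Number of genes.
#' @param n_case,n_control Samples per group (each >= 2).
#' @param n_de Number of planted differential genes (`<= n_genes`).
#' @param effect Planted |log2 fold-change|.
#' @param sigma Within-group standard deviation (log2 units).
#' @param seed Integer seed.
#' @return A list with elements `expr` (an [expression_matrix()]) and
#'   `truth` (list with `de_genes`: data.frame of `gene`, `log2fc`).
#' @export
synth_expression <- function(n_genes = 2000, n_case = 4, n_control = 4,
                             n_de = 100, effect = 2, sigma = 0.5,
                             seed = 1) {
  if (n_de > n_genes) stop("n_de must not exceed n_genes")
  if (sigma <= 0) stop("sigma must be positive")
  if (n_case < 2 || n_control < 2) stop("need >= 2 samples per group")
  set.seed(derive_seed(seed, "expression"))
  genes <- sprintf("G%05d", seq_len(n_genes))
  samples <- c(sprintf("case_%02d", seq_len(n_case)),
               sprintf("ctrl_%02d", seq_len(n_control)))
  groups <- setNames(rep(c("unstable", "stable"), c(n_case, n_control)),
                     samples)
  base_mean <- stats::rnorm(n_genes, mean = 7, sd = 1.5)
  vals <- base_mean + matrix(stats::rnorm(n_genes * length(samples),
                                          sd = sigma),
                             n_genes, length(samples))
  de <- data.frame(gene = character(), log2fc = numeric(),
                   stringsAsFactors = FALSE)
  if (n_de > 0 && effect != 0) {
    idx <- sort(sample.int(n_genes, n_de))
    sign <- rep(c(1, -1), length.out = n_de)
    vals[idx, seq_len(n_case)] <- vals[idx, seq_len(n_case)] + sign * effect
    de <- data.frame(gene = genes[idx], log2fc = sign * effect,
                     stringsAsFactors = FALSE)
  }
  rownames(vals) <- genes
  colnames(vals) <- samples
  list(expr = expression_matrix(vals, groups),
       truth = list(de_genes = de))
}

#' Simulate a scored PPI edge list with planted dense modules and a hub
#'
#' Planted modules are cliques at confidence 900 (above any plausible build
#' threshold, so graph-threshold behaviour is decoupled from module
#' recovery); background edges are Erdos-Renyi with confidences uniform in
#' \[400, 900\]. One member of the largest module is designated the hub: it
#' is wired to one node of every other module and to `hub_extra` randomly
#' chosen background nodes, mimicking a promiscuous scaffold protein that
#' touches partners across and outside its complexes — without the extra
#' spokes the hub's degree margin over its own module mates would be only
#' the number of other modules, and background noise would routinely
#' overturn its top centrality rank.
#'
#' @param n_nodes Total node count (`>= sum(module_sizes)`).
#' @param module_sizes Integer vector of planted clique sizes (each >= 3).
#' @param p_background Background edge probability in \[0, 1).
#' @param seed Integer seed.
#' @param hub_extra Number of extra hub spokes to background nodes
#'   (default `round(0.05 * n_nodes)`, capped by availability).
#' @param node_ids Optional character vector of node identifiers to use
#'   (length `n_nodes`); defaults to `P0001, P0002, ...`.
#' @return List with `edges` (an [edge_table()]) and `truth` (list with
#'   `modules`: list of character vectors, `hub_gene`, `nodes`).
#' @export
synth_ppi <- function(n_nodes = 200, module_sizes = c(8, 6, 5),
                      p_background = 0.02, seed = 1,
                      hub_extra = round(0.05 * n_nodes), node_ids = NULL) {
  if (sum(module_sizes) > n_nodes)
    stop("sum(module_sizes) must not exceed n_nodes")
  if (any(module_sizes < 3))
    stop("module sizes must be >= 3")
  if (p_background < 0 || p_background >= 1)
    stop("p_background must be in [0, 1)")
  set.seed(derive_seed(seed, "ppi"))
  if (is.null(node_ids)) node_ids <- sprintf("P%04d", seq_len(n_nodes))
  if (length(node_ids) != n_nodes) stop("node_ids must have length n_nodes")
  ord <- order(module_sizes, decreasing = TRUE)
  module_sizes <- module_sizes[ord]
  bounds <- cumsum(module_sizes)
  modules <- lapply(seq_along(module_sizes), function(i) {
    from <- if (i == 1) 1L else bounds[i - 1L] + 1L
    node_ids[from:bounds[i]]
  })
  a <- character(); b <- character(); conf <- integer()
  for (m in modules) {
    pr <- t(utils::combn(m, 2))
    a <- c(a, pr[, 1]); b <- c(b, pr[, 2])
    conf <- c(conf, rep(900L, nrow(pr)))
  }
  hub <- modules[[1]][1]
  if (length(modules) > 1) {
    for (i in 2:length(modules)) {
      tgt <- modules[[i]][1]
      a <- c(a, hub); b <- c(b, tgt); conf <- c(conf, 900L)
    }
  }
  background_nodes <- setdiff(node_ids, unlist(modules))
  hub_extra <- min(hub_extra, length(background_nodes))
  if (hub_extra > 0) {
    spokes <- sample(background_nodes, hub_extra)
    a <- c(a, rep(hub, hub_extra)); b <- c(b, spokes)
    conf <- c(conf, rep(900L, hub_extra))
  }
  if (p_background > 0 && n_nodes >= 2) {
    pairs <- t(utils::combn(node_ids, 2))
    key <- paste(pmin(a, b), pmax(a, b))
    pk <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    free <- !(pk %in% key)
    draw <- free & stats::runif(nrow(pairs)) < p_background
    if (any(draw)) {
      a <- c(a, pairs[draw, 1]); b <- c(b, pairs[draw, 2])
      conf <- c(conf, as.integer(round(stats::runif(sum(draw), 400, 900))))
    }
  }
  list(edges = edge_table(a, b, conf),
       truth = list(modules = modules, hub_gene = hub, nodes = node_ids))
}

#' Simulate drug-target sets at controlled distance from a disease set
#'
#' Proximal drugs draw their targets from the disease set and its direct
#' network neighbours — at least half of each proximal drug's targets come
#' from the disease set itself (direct targeting of disease proteins is
#' what the self-target weight rewards); random drugs draw uniformly from
#' all network nodes.
#'
#' @param edges An [edge_table()] defining the network.
#' @param disease_set Character vector of disease genes (non-empty subset of
#'   the network's nodes).
#' @param n_proximal,n_random Number of proximal / random drugs.
#' @param targets_per_drug Targets drawn per drug.
#' @param seed Integer seed.
#' @return List with `drugs` (a [drug_target_map()]) and `truth` (list with
#'   `proximal_drugs`).
#' @export
synth_drug_targets <- function(edges, disease_set, n_proximal = 5,
                               n_random = 45, targets_per_drug = 3,
                               seed = 1) {
  nodes <- unique(c(edges$gene_a, edges$gene_b))
  disease_set <- intersect(disease_set, nodes)
  if (length(disease_set) == 0)
    stop("disease_set must be a non-empty subset of the network nodes")
  nbr <- unique(c(edges$gene_b[edges$gene_a %in% disease_set],
                  edges$gene_a[edges$gene_b %in% disease_set]))
  pool <- unique(c(disease_set, nbr))
  if (targets_per_drug > length(pool))
    stop("targets_per_drug exceeds the proximal candidate pool")
  if (targets_per_drug > length(nodes))
    stop("targets_per_drug exceeds the node count")
  set.seed(derive_seed(seed, "drugs"))
  targets <- list()
  n_in_set <- min(ceiling(targets_per_drug / 2), length(disease_set))
  for (i in seq_len(n_proximal)) {
    inside <- sample(disease_set, n_in_set)
    rest <- sample(setdiff(pool, inside), targets_per_drug - n_in_set)
    targets[[sprintf("DPROX%03d", i)]] <- sample(c(inside, rest))
  }
  for (i in seq_len(n_random))
    targets[[sprintf("DRAND%03d", i)]] <- sample(nodes, targets_per_drug)
  list(drugs = drug_target_map(targets),
       truth = list(proximal_drugs = sprintf("DPROX%03d",
                                             seq_len(n_proximal))))
}

#' Simulate immune/pathway signatures coupled to a hub gene
#'
#' Signature member genes' expression is rewritten as
#' `coupling * z(hub) + sqrt(1 - coupling^2) * noise` (then rescaled to each
#' gene's original location), so the sample-level correlation between the
#' hub and each member — and hence each signature's ssGSEA score — equals
#' `coupling` in expectation. `coupling = -1` gives exactly rank-reversed
#' scores; `coupling = 0` leaves members independent of the hub.
#'
#' @param expr An [expression_matrix()].
#' @param hub Gene id of the hub (must be measured).
#' @param n_signatures Number of signatures (default 28, the size of the
#'   standard immune-cell signature panel).
#' @param genes_per_sig Member genes per signature.
#' @param coupling Target correlation in \[-1, 0\].
#' @param seed Integer seed.
#' @param exclude Genes never used as signature members (besides the hub).
#' @return List with `signatures` (a [gene_set_collection()]) and `expr`
#'   (the mutated copy of the input matrix).
#' @export
synth_signatures <- function(expr, hub, n_signatures = 28,
                             genes_per_sig = 10, coupling = -0.9,
                             seed = 1, exclude = character()) {
  genes <- rownames(expr$values)
  if (!(hub %in% genes)) stop("hub gene not present in expression matrix")
  if (coupling < -1 || coupling > 0) stop("coupling must be in [-1, 0]")
  avail <- setdiff(genes, c(hub, exclude))
  need <- n_signatures * genes_per_sig
  if (need > length(avail))
    stop("not enough genes for the requested signatures")
  set.seed(derive_seed(seed, "signatures"))
  members <- sample(avail, need)
  sets <- split(members, rep(seq_len(n_signatures), each = genes_per_sig))
  names(sets) <- sprintf("SIG%02d", seq_len(n_signatures))
  h <- expr$values[hub, ]
  hz <- (h - mean(h)) / stats::sd(h)
  vals <- expr$values
  for (g in members) {
    eps <- stats::rnorm(length(h))
    eps <- if (stats::sd(eps) > 0) (eps - mean(eps)) / stats::sd(eps) else eps
    mix <- coupling * hz + sqrt(max(0, 1 - coupling^2)) * eps
    vals[g, ] <- mean(vals[g, ]) + stats::sd(vals[g, ]) * mix
  }
  new_expr <- expression_matrix(vals, expr$groups,
                                case = expr$case, control = expr$control)
  list(signatures = gene_set_collection(sets), expr = new_expr)
}
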