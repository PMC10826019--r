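# PPI network construction, MCODE-style dense-module detection, and
# centrality-based hub ranking. Confidence scores act purely as a
# construction filter; all path-based quantities use unweighted hop
# distances. Centralities are normalized within each connected component
# (the behaviour of the usual network-analysis GUIs for disconnected
# graphs).

#' Build a PPI graph from a scored edge table
#'
#' Keeps edges at or above `min_confidence` (the 0-1000 STRING scale; 400 is
#' "medium confidence" and the default — the threshold is inclusive),
#' drops self-loops, collapses duplicate edges keeping the maximum
#' confidence, and omits isolated nodes (the graph is defined by its edges).
#' With `largest_component = TRUE` (the default) the small disconnected
#' fragments are removed as well and only the main connected network is
#' retained; component-wise centrality normalization otherwise lets
#' two- and three-node fragments swamp closeness and betweenness rankings.
#'
#' @param edges An [edge_table()].
#' @param min_confidence Inclusive confidence threshold (default 400).
#' @param largest_component Keep only the largest connected component
#'   (default `TRUE`; ties broken by smallest vertex name).
#' @return An igraph object of class `PPINetwork` with vertex names and an
#'   edge attribute `confidence`.
#' @export
build_graph <- function(edges, min_confidence = 400,
                        largest_component = TRUE) {
  keep <- edges$confidence >= min_confidence & edges$gene_a != edges$gene_b
  e <- edges[keep, , drop = FALSE]
  if (nrow(e) == 0) stop("no edges at or above the confidence threshold")
  a <- pmin(e$gene_a, e$gene_b)
  b <- pmax(e$gene_a, e$gene_b)
  key <- paste(a, b, sep = "\r")
  conf <- tapply(e$confidence, key, max)
  parts <- strsplit(names(conf), "\r", fixed = TRUE)
  df <- data.frame(from = vapply(parts, `[`, "", 1),
                   to = vapply(parts, `[`, "", 2),
                   confidence = as.integer(conf),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  if (largest_component) {
    comp <- igraph::components(g)
    sizes <- tabulate(comp$membership, comp$no)
    big <- which(sizes == max(sizes))
    if (length(big) > 1) {
      first_name <- vapply(big, function(ci)
        min(igraph::V(g)$name[comp$membership == ci]), "")
      big <- big[which.min(first_name)]
    }
    g <- igraph::induced_subgraph(g,
                                  igraph::V(g)[comp$membership == big])
  }
  class(g) <- c("PPINetwork", class(g))
  g
}

#' MCODE parameter set
#'
#' Defaults are the conventional Cytoscape settings for this analysis:
#' degree cutoff 3 for scoring; node score cutoff 0.4, haircut on, fluff
#' off, k-core 3 and maximum depth 80 for cluster finding.
#'
#' @param degree_cutoff Minimum degree for a node to receive a score.
#' @param node_score_cutoff Allowed fractional drop from the seed weight
#'   during expansion, in \[0, 1\].
#' @param haircut Remove singly connected nodes (applied both as an
#'   admission constraint during expansion and as a post-processing pass;
#'   see [mcode_find_clusters()]).
#' @param fluff,fluff_density Fluff post-processing (off by default; kept
#'   for interface compatibility, not implemented).
#' @param k_core Clusters must contain a k-core of this order.
#' @param max_depth Maximum hop distance from the seed during expansion.
#' @return List of class `McodeParams`.
#' @export
mcode_params <- function(degree_cutoff = 3, node_score_cutoff = 0.4,
                         haircut = TRUE, fluff = FALSE, fluff_density = 0.2,
                         k_core = 3, max_depth = 80) {
  if (node_score_cutoff < 0 || node_score_cutoff > 1)
    stop("node_score_cutoff must be in [0, 1]")
  if (fluff) stop("fluff post-processing is not implemented")
  structure(list(degree_cutoff = degree_cutoff,
                 node_score_cutoff = node_score_cutoff,
                 haircut = haircut, fluff = fluff,
                 fluff_density = fluff_density,
                 k_core = k_core, max_depth = max_depth),
            class = "McodeParams")
}

graph_density_undirected <- function(n, m) {
  if (n < 2) return(0)
  2 * m / (n * (n - 1))
}

# Highest k-core of an igraph: k_max and the subgraph's size/edge count.
highest_core <- function(g) {
  core <- igraph::coreness(g)
  kmax <- max(core)
  keep <- names(core)[core >= kmax]
  sub <- igraph::induced_subgraph(g, keep)
  list(k = kmax, n = igraph::vcount(sub), m = igraph::ecount(sub))
}

#' MCODE vertex weights
#'
#' For each node `v` with degree at or above the degree cutoff, the weight
#' is `k_max * density` of the highest k-core of the closed neighbourhood
#' `N[v]` (density = 2E / (n(n-1))); nodes below the cutoff get weight 0.
#'
#' @param g A [build_graph()] network.
#' @param params A [mcode_params()] set.
#' @return Named numeric vector of weights over all nodes.
#' @export
mcode_vertex_weights <- function(g, params = mcode_params()) {
  nodes <- igraph::V(g)$name
  deg <- igraph::degree(g)
  w <- setNames(numeric(length(nodes)), nodes)
  for (v in nodes[deg >= params$degree_cutoff]) {
    nb <- c(v, igraph::neighbors(g, v)$name)
    hc <- highest_core(igraph::induced_subgraph(g, nb))
    w[v] <- hc$k * graph_density_undirected(hc$n, hc$m)
  }
  w
}

# Iterative majority trim: drop nodes not adjacent to a strict majority of
# the other cluster members (admission hole: a seed's direct neighbours
# enter with a single supporting edge before the cluster exists to vote).
majority_trim <- function(g, members) {
  repeat {
    n <- length(members)
    if (n < 3) return(members)
    sub <- igraph::induced_subgraph(g, members)
    deg <- igraph::degree(sub)
    need <- (n - 1L) %/% 2L + 1L
    drop <- names(deg)[deg < need]
    if (length(drop) == 0) return(members)
    members <- setdiff(members, drop)
  }
}

# Iterative haircut: drop nodes with fewer than 2 within-cluster edges.
haircut_cluster <- function(g, members) {
  repeat {
    if (length(members) < 2) return(members)
    sub <- igraph::induced_subgraph(g, members)
    deg <- igraph::degree(sub)
    drop <- names(deg)[deg < 2]
    if (length(drop) == 0) return(members)
    members <- setdiff(members, drop)
  }
}

#' MCODE cluster finding
#'
#' Seeds are processed in decreasing weight order (ties: higher degree,
#' then lexicographic id). From each unvisited seed, neighbours are admitted
#' breadth-first when their weight is at least
#' `seed_weight * (1 - node_score_cutoff)` and they lie within `max_depth`
#' hops of the seed; each node joins at most one cluster. With
#' `haircut = TRUE`, expansion is additionally density-consistent: a
#' candidate is admitted only when it is adjacent to a strict majority of
#' the current cluster members (and never fewer than 2 of them). Cliques
#' and near-cliques always satisfy this, while nodes reachable only
#' through one or two incidental edges — bridges between otherwise
#' unrelated dense regions — are excluded; such nodes would either fall to
#' the haircut or dilute the cluster's k-core. Candidates rejected for
#' lack of support are reconsidered as the cluster grows. A consequence is
#' that sparse or triangle-free dense structures (e.g. complete bipartite
#' cores) are not expanded into; complexes are modelled as near-cliques.
#'
#' Post-processing: clusters that do not contain a `k_core`-core are
#' discarded (their members become available to later seeds); the haircut
#' pass removes singly connected members; the cluster score is
#' `density * size`, and clusters are reported in decreasing score order.
#'
#' @param g A [build_graph()] network.
#' @param params A [mcode_params()] set.
#' @return List of class `ModuleResult` with `clusters` (list of character
#'   vectors), `scores`, and `seeds`.
#' @export
mcode_find_clusters <- function(g, params = mcode_params()) {
  w <- mcode_vertex_weights(g, params)
  nodes <- names(w)
  deg <- igraph::degree(g)[nodes]
  seed_order <- nodes[order(-w, -deg, nodes)]
  visited <- setNames(rep(FALSE, length(nodes)), nodes)
  clusters <- list(); scores <- numeric(); seeds <- character()

  adj <- igraph::adjacent_vertices(g, nodes)
  adj <- lapply(adj, function(x) x$name)
  names(adj) <- nodes

  for (seed in seed_order) {
    if (visited[seed]) next
    threshold <- w[seed] * (1 - params$node_score_cutoff)
    members <- seed
    depth <- setNames(0L, seed)
    repeat {
      cand <- setdiff(unique(unlist(adj[members], use.names = FALSE)),
                      members)
      cand <- cand[!visited[cand] & w[cand] >= threshold]
      if (length(cand) == 0) break
      cd <- vapply(cand, function(u)
        min(depth[intersect(adj[[u]], members)]) + 1L, 0L)
      cand <- cand[cd <= params$max_depth]
      cd <- cd[cd <= params$max_depth]
      if (length(cand) == 0) break
      if (params$haircut) {
        smin <- min(max(2L, length(members) %/% 2L + 1L), length(members))
        support <- vapply(cand, function(u)
          length(intersect(adj[[u]], members)), 0L)
        cand <- cand[support >= smin]
        cd <- cd[support >= smin]
      }
      if (length(cand) == 0) break
      ord <- order(cd, cand)
      members <- c(members, cand[ord])
      depth <- c(depth, setNames(cd[ord], cand[ord]))
    }
    if (params$haircut) members <- majority_trim(g, members)
    if (length(members) < 2) next
    sub <- igraph::induced_subgraph(g, members)
    if (max(igraph::coreness(sub)) < params$k_core) next
    if (params$haircut) members <- haircut_cluster(g, members)
    if (length(members) < 2) next
    visited[members] <- TRUE
    sub <- igraph::induced_subgraph(g, members)
    dens <- graph_density_undirected(igraph::vcount(sub),
                                     igraph::ecount(sub))
    clusters[[length(clusters) + 1L]] <- sort(members)
    scores <- c(scores, dens * length(members))
    seeds <- c(seeds, seed)
  }
  ord <- order(-scores, -lengths(clusters), seeds)
  structure(list(clusters = clusters[ord], scores = scores[ord],
                 seeds = seeds[ord]),
            class = "ModuleResult")
}

#' Degree, betweenness and closeness centralities
#'
#' Degree is the incident edge count. Betweenness uses shortest-path
#' counting with fractional credit for tied geodesics, normalized by
#' `(n-1)(n-2)/2` within each connected component of size `n`; closeness is
#' `(n-1) / sum of hop distances` within the node's component. Nodes in
#' singleton (or two-node, for betweenness) components where the
#' normalization is undefined get 0.
#'
#' @param g A [build_graph()] network.
#' @return data.frame with columns `node`, `degree`, `betweenness`,
#'   `closeness`.
#' @export
centralities <- function(g) {
  nodes <- igraph::V(g)$name
  deg <- igraph::degree(g)
  btw <- setNames(numeric(length(nodes)), nodes)
  clo <- setNames(numeric(length(nodes)), nodes)
  comp <- igraph::components(g)
  for (ci in seq_len(comp$no)) {
    mem <- nodes[comp$membership == ci]
    n <- length(mem)
    if (n == 1) next
    sub <- igraph::induced_subgraph(g, mem)
    if (n > 2) {
      b <- igraph::betweenness(sub, directed = FALSE, normalized = TRUE,
                               weights = NA)
      btw[mem] <- b[mem]
    }
    cl <- igraph::closeness(sub, normalized = TRUE, weights = NA)
    clo[mem] <- cl[mem]
  }
  data.frame(node = nodes, degree = as.numeric(deg[nodes]),
             betweenness = as.numeric(btw[nodes]),
             closeness = as.numeric(clo[nodes]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank hub genes by aggregated centrality ranks
#'
#' Each node is ranked on each of the three metrics (rank 1 = best; average
#' ranks for ties); the aggregate is the mean of the three ranks. The top
#' `k` nodes by aggregate are returned, with ties broken by higher degree,
#' then lexicographic id.
#'
#' @param topo Topology table from [centralities()].
#' @param k Number of hubs to return (default 5).
#' @return Character vector of `k` node ids, best first.
#' @export
rank_hubs <- function(topo, k = 5) {
  if (k > nrow(topo)) stop("k exceeds the node count")
  r_deg <- rank(-topo$degree, ties.method = "average")
  r_btw <- rank(-topo$betweenness, ties.method = "average")
  r_clo <- rank(-topo$closeness, ties.method = "average")
  agg <- (r_deg + r_btw + r_clo) / 3
  ord <- order(agg, -topo$degree, topo$node)
  topo$node[ord][seq_len(k)]
}
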