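# Over-representation analysis of a query gene set against a user-supplied
# annotation collection. The universe defaults to the measured genes (not
# the genome): enrichment of screened genes is judged against the assayed
# background. One-sided (over-representation) tests only.

#' Hypergeometric over-representation test
#'
#' For each annotation set of size K (after intersection with the universe
#' of size N), the overlap k with the query of size n is scored by the
#' hypergeometric upper tail \eqn{p = P[X \ge k]}; BH adjustment is applied
#' across all tested sets. Sets empty after intersection with the universe
#' are skipped. Query genes outside the universe are dropped with a warning.
#'
#' @param query Character vector of query gene ids.
#' @param annotations A [gene_set_collection()].
#' @param universe Character vector of background gene ids.
#' @return data.frame with columns `set`, `k`, `K`, `n`, `N`, `p`, `fdr`,
#'   ordered as in the collection.
#' @export
ora_test <- function(query, annotations, universe) {
  universe <- unique(trimws(as.character(universe)))
  if (length(universe) == 0) stop("empty universe")
  query <- unique(trimws(as.character(query)))
  outside <- setdiff(query, universe)
  if (length(outside))
    warning(length(outside), " query gene(s) outside the universe dropped")
  query <- intersect(query, universe)
  if (length(query) == 0) stop("query empty after intersection with universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(annotations$sets), function(nm) {
    set <- intersect(annotations$sets[[nm]], universe)
    K <- length(set)
    if (K == 0) return(NULL)
    k <- length(intersect(set, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE))
  out$fdr <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
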