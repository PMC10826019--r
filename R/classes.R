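#' Construct an expression matrix with two-group sample labels
#'
#' The central container of the pipeline: a genes x samples matrix of
#' log2-scale expression values together with a case/control label for every
#' sample. All downstream stages (differential expression, diagnostics,
#' ssGSEA, correlations) consume this object.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Values are assumed to be
#'   on the log2 scale already.
#' @param groups Named character vector mapping every sample id to its group
#'   label; exactly two distinct labels must be present.
#' @param case Label of the case group (default `"unstable"`).
#' @param control Label of the control group (default `"stable"`).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `groups`, `case`, `control`.
#' @export
expression_matrix <- function(values, groups,
                              case = "unstable", control = "stable") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("samples missing from group labels: ",
         paste(missing, collapse = ", "))
  groups <- groups[colnames(values)]
  bad <- setdiff(unique(groups), c(case, control))
  if (length(bad))
    stop("unknown group labels: ", paste(bad, collapse = ", "))
  if (!any(groups == case) || !any(groups == control))
    stop("both groups must be non-empty")
  structure(list(values = values, groups = groups,
                 case = case, control = control),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d %s / %d %s)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == x$case), x$case,
              sum(x$groups == x$control), x$control))
  invisible(x)
}

#' Sample ids of the case / control group
#'
#' @param expr An [expression_matrix()].
#' @return Character vector of sample ids.
#' @export
case_samples <- function(expr) names(expr$groups)[expr$groups == expr$case]

#' @rdname case_samples
#' @export
control_samples <- function(expr) {
  names(expr$groups)[expr$groups == expr$control]
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (one gene set per element);
#'   genes within a set are deduplicated.
#' @param descriptions Optional named character vector of free-text
#'   descriptions; defaults to empty strings.
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a named list")
  if (anyDuplicated(names(sets)))
    stop("duplicate set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  if (any(lengths(sets) == 0))
    stop("empty gene sets: ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  } else {
    descriptions <- descriptions[names(sets)]
    descriptions[is.na(descriptions)] <- ""
    names(descriptions) <- names(sets)
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets (sizes %s)\n", length(x$sets),
              paste(range(lengths(x$sets)), collapse = "-")))
  invisible(x)
}

#' Construct a scored edge table
#'
#' Edges carry STRING-style integer confidences on the 0-1000 scale; the
#' conventional "0.4" confidence threshold corresponds to 400 here and is
#' applied at [build_graph()], not at parse time.
#'
#' @param gene_a,gene_b Character vectors of endpoint identifiers.
#' @param confidence Integer vector of confidences in \[0, 1000\].
#' @return A `data.frame` of class `EdgeTable` with columns
#'   `gene_a`, `gene_b`, `confidence`.
#' @export
edge_table <- function(gene_a = character(), gene_b = character(),
                       confidence = integer()) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  if (length(gene_a) != length(gene_b) ||
      length(gene_a) != length(confidence))
    stop("endpoint and confidence vectors must have equal length")
  if (any(!nzchar(gene_a)) || any(!nzchar(gene_b)))
    stop("edge endpoints must be non-empty identifiers")
  conf <- as.integer(round(as.numeric(confidence)))
  if (any(is.na(conf)) || any(conf < 0L) || any(conf > 1000L))
    stop("confidence values must be integers in [0, 1000]")
  structure(data.frame(gene_a = gene_a, gene_b = gene_b,
                       confidence = conf, stringsAsFactors = FALSE),
            class = c("EdgeTable", "data.frame"))
}

#' Construct a drug -> target-gene map
#'
#' @param targets Named list: drug id -> character vector of target gene ids
#'   (deduplicated; must be non-empty).
#' @return An object of class `DrugTargetMap` (a named list).
#' @export
drug_target_map <- function(targets) {
  if (!is.list(targets) || is.null(names(targets)) ||
      any(names(targets) == ""))
    stop("`targets` must be a named list")
  if (anyDuplicated(names(targets)))
    stop("duplicate drug ids")
  targets <- lapply(targets, function(g) unique(as.character(g)))
  if (any(lengths(targets) == 0))
    stop("drugs with empty target sets: ",
         paste(names(targets)[lengths(targets) == 0], collapse = ", "))
  structure(targets, class = "DrugTargetMap")
}

#' @export
print.DrugTargetMap <- function(x, ...) {
  cat(sprintf("DrugTargetMap: %d drugs, %d-%d targets each\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}
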