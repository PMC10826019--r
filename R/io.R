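# Readers and writers for the plain-text formats the pipeline consumes:
# expression TSV + label TSV, GMT gene-set collections, three-column scored
# edge lists, two-column drug-target tables. TSV only, UTF-8, no missing
# values: "NA"/empty cells are hard errors rather than silently imputed,
# because silent imputation would corrupt the rank statistics downstream.

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

#' Read an expression matrix and its sample labels
#'
#' The matrix file is a TSV with a header row of sample ids and gene ids in
#' the first column; the labels file is a two-column TSV (sample id, group
#' label) without a header. Row and column order are preserved from file.
#'
#' @param path Path to the expression TSV.
#' @param labels_path Path to the two-column sample-label TSV.
#' @param case,control Group labels designating case and control samples.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, labels_path,
                            case = "unstable", control = "stable") {
  lines <- read_tsv_lines(path)
  if (length(lines) < 2) stop("expression file needs a header and >=1 gene")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (length(samples) == 0) stop("expression file has no sample columns")
  n <- length(lines) - 1L
  genes <- character(n)
  vals <- matrix(NA_real_, n, length(samples))
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(samples) + 1L)
      stop(sprintf("line %d: expected %d fields, found %d",
                   i + 1L, length(samples) + 1L, length(f)))
    genes[i] <- f[1]
    cells <- f[-1]
    bad <- which(cells == "" | toupper(cells) == "NA")
    if (length(bad))
      stop(sprintf("missing value at gene '%s' (row %d), sample '%s'",
                   f[1], i, samples[bad[1]]))
    num <- suppressWarnings(as.numeric(cells))
    if (any(is.na(num)))
      stop(sprintf("non-numeric value '%s' at gene '%s' (row %d), sample '%s'",
                   cells[which(is.na(num))[1]], f[1], i,
                   samples[which(is.na(num))[1]]))
    vals[i, ] <- num
  }
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  rownames(vals) <- genes
  colnames(vals) <- samples
  lab_lines <- read_tsv_lines(labels_path)
  lab_lines <- lab_lines[nzchar(lab_lines)]
  lab <- strsplit(lab_lines, "\t", fixed = TRUE)
  if (any(lengths(lab) != 2)) stop("labels file must have two columns")
  groups <- setNames(vapply(lab, `[`, "", 2), vapply(lab, `[`, "", 1))
  expression_matrix(vals, groups, case = case, control = control)
}

#' Write an expression matrix (and optionally its labels) to TSV
#'
#' Values are written as full-precision decimal text so that a
#' write-then-read round trip is exact.
#'
#' @param expr An [expression_matrix()].
#' @param path Output TSV path.
#' @param labels_path Optional path for the two-column label TSV.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path, labels_path = NULL) {
  v <- expr$values
  txt <- matrix(num_text(v), nrow(v))
  lines <- c(paste(c("gene", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(rownames(v)[i], txt[i, ]), collapse = "\t"), ""))
  writeLines(lines, path, useBytes = TRUE)
  if (!is.null(labels_path))
    writeLines(paste(names(expr$groups), expr$groups, sep = "\t"),
               labels_path, useBytes = TRUE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Each line is `name TAB description TAB gene1 TAB gene2 ...`; duplicate
#' genes within a line are collapsed.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  nm <- vapply(fields, `[`, "", 1)
  if (anyDuplicated(nm))
    stop("duplicate set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  desc <- setNames(vapply(fields, `[`, "", 2), nm)
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection to GMT
#'
#' @param gsc A [gene_set_collection()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm)
    paste(c(nm, gsc$descriptions[[nm]], gsc$sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a scored edge list
#'
#' TSV with columns `gene_a`, `gene_b`, `confidence` (0-1000 integer scale);
#' a header line is detected and skipped if its third field is non-numeric.
#' An empty file yields an empty table (whether that is an error is decided
#' by [build_graph()]).
#'
#' @param path Path to the edge TSV.
#' @return An [edge_table()].
#' @export
read_edge_list <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(edge_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (is.na(suppressWarnings(as.numeric(fields[[1]][3])))) {
    fields <- fields[-1]
    if (length(fields) == 0) return(edge_table())
  }
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop(sprintf("edge list line %d has fewer than 3 columns", short[1]))
  a <- vapply(fields, `[`, "", 1)
  b <- vapply(fields, `[`, "", 2)
  conf <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  if (any(is.na(conf)))
    stop(sprintf("non-numeric confidence at line %d", which(is.na(conf))[1]))
  if (any(conf < 0 | conf > 1000))
    stop(sprintf("confidence out of [0, 1000] at line %d",
                 which(conf < 0 | conf > 1000)[1]))
  edge_table(a, b, conf)
}

#' Write an edge table to TSV
#'
#' @param edges An [edge_table()].
#' @param path Output path.
#' @param header Write a header line (default `TRUE`).
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(edges, path, header = TRUE) {
  lines <- paste(edges$gene_a, edges$gene_b, edges$confidence, sep = "\t")
  if (header) lines <- c("gene_a\tgene_b\tconfidence", lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a drug-target table
#'
#' TSV with columns `drug_id`, `gene_id`, one pair per line (optional
#' header); pairs are grouped by drug and duplicates collapsed.
#'
#' @param path Path to the TSV.
#' @return A [drug_target_map()].
#' @export
read_drug_targets <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty drug-target file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(tolower(fields[[1]][1]), "drug_id")) fields <- fields[-1]
  bad <- which(lengths(fields) < 2)
  if (length(bad))
    stop(sprintf("drug-target line %d has fewer than 2 columns", bad[1]))
  drug <- vapply(fields, `[`, "", 1)
  gene <- vapply(fields, `[`, "", 2)
  if (any(!nzchar(drug)) || any(!nzchar(gene)))
    stop(sprintf("blank drug or gene field at line %d",
                 which(!nzchar(drug) | !nzchar(gene))[1]))
  drug_target_map(split(gene, factor(drug, levels = unique(drug))))
}

#' Write a drug-target map to TSV
#'
#' @param drugs A [drug_target_map()].
#' @param path Output path.
#' @param header Write a header line (default `TRUE`).
#' @return Invisibly, `path`.
#' @export
write_drug_targets <- function(drugs, path, header = TRUE) {
  lines <- unlist(lapply(names(drugs), function(d)
    paste(d, drugs[[d]], sep = "\t")), use.names = FALSE)
  if (header) lines <- c("drug_id\tgene_id", lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a one-identifier-per-line gene list
#'
#' @param path Path to the text file; blank lines are ignored, identifiers
#'   are whitespace-stripped.
#' @return Character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(read_tsv_lines(path))
  unique(x[nzchar(x)])
}
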