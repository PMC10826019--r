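# End-to-end orchestration: simulate (or load) the five inputs, then run
# differential expression -> disease-gene intersection -> enrichment ->
# network/modules/hubs -> per-gene diagnostics -> ssGSEA + correlations +
# anchor-related genes -> drug proximity -> screening, writing every
# stage's TSV plus a machine-readable summary.json. All randomness is
# driven by one integer seed through named substreams, so identical
# configurations yield byte-identical outputs.

#' Pipeline configuration
#'
#' Collects every tunable threshold with its conventional default:
#' `lfc_min = 1`, `fdr_max = 0.05`, `min_confidence = 400`, the MCODE
#' quartet (node score cutoff 0.4, haircut on, fluff off, k-core 3),
#' `r_min = 0.9`, `p_max = 0.001`, `d_max = 1.2`,
#' `n_permutations = 10000`.
#'
#' @param lfc_min DEG |log2FC| threshold (strict).
#' @param fdr_max FDR gate used for DEG screening and drug screening.
#' @param min_confidence Edge confidence threshold (0-1000, inclusive).
#' @param mcode An [mcode_params()] set.
#' @param n_hubs Hub genes to report.
#' @param r_min,p_max Anchor-related gene thresholds (strict).
#' @param d_max Drug-distance screening threshold (strict).
#' @param n_permutations Permutations for the proximity null.
#' @param svm_c SVM box constraint.
#' @param ssgsea_alpha ssGSEA rank-weight exponent.
#' @param seed Global integer seed.
#' @param simulate List of arguments forwarded to [simulate_inputs()]
#'   (or `NULL` when `paths` is given).
#' @param paths Named list of input paths (`expression`, `labels`,
#'   `disease_genes`, `edges`, `signatures`, `drug_targets`) when running
#'   on real data.
#' @return List of class `RunConfig`.
#' @export
pipeline_config <- function(lfc_min = 1, fdr_max = 0.05,
                            min_confidence = 400,
                            mcode = mcode_params(), n_hubs = 5,
                            r_min = 0.9, p_max = 0.001, d_max = 1.2,
                            n_permutations = 10000, svm_c = 1,
                            ssgsea_alpha = 0.25, seed = 1,
                            simulate = list(), paths = NULL) {
  cfg <- list(lfc_min = lfc_min, fdr_max = fdr_max,
              min_confidence = min_confidence, mcode = mcode,
              n_hubs = n_hubs, r_min = r_min, p_max = p_max,
              d_max = d_max, n_permutations = n_permutations,
              svm_c = svm_c, ssgsea_alpha = ssgsea_alpha, seed = seed,
              simulate = simulate, paths = paths)
  validate_config(cfg)
  structure(cfg, class = "RunConfig")
}

validate_config <- function(cfg) {
  stopifnot_msg <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  stopifnot_msg(cfg$lfc_min > 0, "lfc_min must be positive")
  stopifnot_msg(cfg$fdr_max > 0 && cfg$fdr_max <= 1,
                "fdr_max must be in (0, 1]")
  stopifnot_msg(cfg$min_confidence >= 0 && cfg$min_confidence <= 1000,
                "min_confidence must be in [0, 1000]")
  stopifnot_msg(cfg$r_min > 0 && cfg$r_min < 1, "r_min must be in (0, 1)")
  stopifnot_msg(cfg$p_max > 0 && cfg$p_max <= 1, "p_max must be in (0, 1]")
  stopifnot_msg(cfg$n_permutations >= 1, "n_permutations must be >= 1")
  stopifnot_msg(is.numeric(cfg$seed) && length(cfg$seed) == 1,
                "seed must be a single integer")
  invisible(TRUE)
}

#' Simulate the five pipeline input files plus a ground-truth record
#'
#' Generates a two-group expression matrix with planted fold-changes, a PPI
#' edge list with planted clique modules and a designated hub, a disease
#' gene list (planted module genes plus planted differential genes), immune
#' signatures negatively coupled to the hub, and drug-target sets planted
#' near the hub's module. The hub's module mates are additionally
#' co-expressed with the hub (correlation ~0.95) so that the anchor-related
#' gene set recovers the module. Files written: `expression.tsv`,
#' `labels.tsv`, `disease_genes.txt`, `edges.tsv`, `signatures.gmt`,
#' `drug_targets.tsv`, `truth.json`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_genes,n_case,n_control,n_de,effect,sigma See
#'   [synth_expression()].
#' @param n_nodes,module_sizes,p_background See [synth_ppi()].
#' @param n_signatures,genes_per_sig,coupling See [synth_signatures()].
#' @param n_proximal,n_random,targets_per_drug See [synth_drug_targets()].
#' @return Invisibly, a list with the generated objects and `truth`.
#' @export
simulate_inputs <- function(dir, seed = 1,
                            n_genes = 2000, n_case = 4, n_control = 4,
                            n_de = 100, effect = 2, sigma = 0.5,
                            n_nodes = 200, module_sizes = c(8, 6, 5),
                            p_background = 0.02,
                            n_signatures = 28, genes_per_sig = 10,
                            coupling = -0.9,
                            n_proximal = 5, n_random = 45,
                            targets_per_drug = 3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  se <- synth_expression(n_genes, n_case, n_control, n_de, effect, sigma,
                         seed = seed)
  expr <- se$expr
  genes <- rownames(expr$values)
  if (n_nodes > n_genes) stop("n_nodes must not exceed n_genes")
  sp <- synth_ppi(n_nodes, module_sizes, p_background, seed = seed,
                  node_ids = genes[seq_len(n_nodes)])
  hub <- sp$truth$hub_gene
  hub_module <- sp$truth$modules[[1]]

  # The hub is planted down in the case group (its module mates inherit the
  # shift through co-expression below), so the hub genes carry diagnostic
  # signal and appear among the screened DEGs. Any fold-change the random
  # DE planting already gave the hub is netted out first.
  vals <- expr$values
  de <- se$truth$de_genes
  prior <- if (hub %in% de$gene) de$log2fc[match(hub, de$gene)] else 0
  vals[hub, expr$groups == expr$case] <-
    vals[hub, expr$groups == expr$case] - effect - prior
  expr <- expression_matrix(vals, expr$groups,
                            case = expr$case, control = expr$control)

  # Co-express the hub's module mates with the hub so the anchor-related
  # set recovers the module.
  set.seed(derive_seed(seed, "module_coexpression"))
  h <- expr$values[hub, ]
  hz <- (h - mean(h)) / stats::sd(h)
  cpl <- 0.97
  vals <- expr$values
  for (gx in setdiff(hub_module, hub)) {
    eps <- stats::rnorm(length(h))
    eps <- (eps - mean(eps)) / stats::sd(eps)
    vals[gx, ] <- mean(vals[gx, ]) + stats::sd(vals[gx, ]) *
      (cpl * hz + sqrt(1 - cpl^2) * eps)
  }
  expr <- expression_matrix(vals, expr$groups,
                            case = expr$case, control = expr$control)

  ss <- synth_signatures(expr, hub, n_signatures, genes_per_sig, coupling,
                         seed = seed, exclude = genes[seq_len(n_nodes)])
  expr <- ss$expr
  disease_genes <- unique(c(unlist(sp$truth$modules), se$truth$de_genes$gene))
  sd_ <- synth_drug_targets(sp$edges, hub_module,
                            n_proximal = n_proximal, n_random = n_random,
                            targets_per_drug = targets_per_drug,
                            seed = seed)

  write_expression(expr, file.path(dir, "expression.tsv"),
                   file.path(dir, "labels.tsv"))
  writeLines(disease_genes, file.path(dir, "disease_genes.txt"))
  write_edge_list(sp$edges, file.path(dir, "edges.tsv"))
  write_gmt(ss$signatures, file.path(dir, "signatures.gmt"))
  write_drug_targets(sd_$drugs, file.path(dir, "drug_targets.tsv"))
  # Rows rewritten after planting (hub, its co-expressed mates, signature
  # members) no longer carry their originally planted fold-changes; the
  # truth record reflects the final matrix.
  rewritten <- c(setdiff(hub_module, hub),
                 unlist(ss$signatures$sets, use.names = FALSE))
  de_truth <- de[!(de$gene %in% c(rewritten, hub)), , drop = FALSE]
  de_truth <- rbind(de_truth,
                    data.frame(gene = hub, log2fc = -effect,
                               stringsAsFactors = FALSE))
  truth <- list(de_genes = de_truth,
                modules = sp$truth$modules,
                hub_gene = hub,
                proximal_drugs = sd_$truth$proximal_drugs,
                coupling = coupling)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(expr = expr, edges = sp$edges,
                 disease_genes = disease_genes,
                 signatures = ss$signatures, drugs = sd_$drugs,
                 truth = truth))
}

write_stage_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  for (j in which(num)) out[[j]] <- num_text(df[[j]])
  lines <- c(paste(names(out), collapse = "\t"),
             do.call(paste, c(unname(as.list(out)), sep = "\t")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes every stage on the configured inputs (simulated into
#' `out_dir/inputs` when `config$paths` is `NULL`, then read back from
#' disk so each stage consumes exactly what a standalone run would) and
#' writes the stage outputs plus `summary.json` into `out_dir`. Identical
#' configuration and seed produce byte-identical outputs. Any stage error
#' aborts with a stage-named message and leaves a `FAILED` marker file.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the run summary list.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out_dir, "FAILED")
  if (file.exists(marker)) unlink(marker)
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)), marker)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    if (is.null(config$paths)) {
      stage <- "simulate"
      args <- c(list(dir = file.path(out_dir, "inputs"),
                     seed = config$seed), config$simulate)
      do.call(simulate_inputs, args)
      paths <- list(
        expression = file.path(out_dir, "inputs", "expression.tsv"),
        labels = file.path(out_dir, "inputs", "labels.tsv"),
        disease_genes = file.path(out_dir, "inputs", "disease_genes.txt"),
        edges = file.path(out_dir, "inputs", "edges.tsv"),
        signatures = file.path(out_dir, "inputs", "signatures.gmt"),
        drug_targets = file.path(out_dir, "inputs", "drug_targets.tsv"))
    } else paths <- config$paths

    stage <- "load"
    expr <- read_expression(paths$expression, paths$labels)
    disease_genes <- read_gene_list(paths$disease_genes)
    edges <- read_edge_list(paths$edges)
    signatures <- read_gmt(paths$signatures)
    drugs <- read_drug_targets(paths$drug_targets)

    stage <- "degs"
    fit <- fit_moderated_t(expr)
    write_stage_tsv(fit$table, file.path(out_dir, "deg_table.tsv"))
    degs <- screen_degs(fit$table, config$lfc_min, config$fdr_max)
    related_degs <- intersect_sets(degs, disease_genes)
    writeLines(related_degs, file.path(out_dir, "as_related_degs.txt"))

    stage <- "enrich"
    ora <- ora_test(related_degs, signatures, rownames(expr$values))
    write_stage_tsv(ora, file.path(out_dir, "ora_results.tsv"))

    stage <- "network"
    g <- build_graph(edges, config$min_confidence)
    modules <- mcode_find_clusters(g, config$mcode)
    mod_df <- data.frame(
      cluster = seq_along(modules$clusters),
      score = modules$scores,
      size = lengths(modules$clusters),
      seed_node = modules$seeds,
      members = vapply(modules$clusters, paste, "", collapse = ","),
      stringsAsFactors = FALSE)
    write_stage_tsv(mod_df, file.path(out_dir, "clusters.tsv"))

    stage <- "hubs"
    topo <- centralities(g)
    hubs <- rank_hubs(topo, min(config$n_hubs, nrow(topo)))
    write_stage_tsv(topo, file.path(out_dir, "topology.tsv"))
    writeLines(hubs, file.path(out_dir, "hub_genes.txt"))
    anchor <- hubs[1]

    stage <- "diagnose"
    labels <- expr$groups[colnames(expr$values)] == expr$case
    diag_rows <- lapply(hubs, function(gene) {
      sc <- expr$values[gene, ]
      wt <- wilcoxon_exact(sc[labels], sc[!labels])
      rc <- roc_auc(sc, labels)
      data.frame(gene = gene, wilcoxon_p = wt$p, auc = rc$auc,
                 auc_direction_free = rc$auc_direction_free,
                 stringsAsFactors = FALSE)
    })
    write_stage_tsv(do.call(rbind, diag_rows),
                    file.path(out_dir, "diagnostics.tsv"))
    feat <- t(expr$values[hubs, , drop = FALSE])
    loo <- loocv_scores(feat, labels, C = config$svm_c)
    loo_auc <- roc_auc(loo, labels)
    write_stage_tsv(data.frame(sample = colnames(expr$values),
                               label = as.integer(labels),
                               loocv_score = loo,
                               stringsAsFactors = FALSE),
                    file.path(out_dir, "svm_loocv.tsv"))

    stage <- "immune"
    scores <- ssgsea_scores(expr, signatures, alpha = config$ssgsea_alpha)
    score_df <- data.frame(signature = rownames(scores),
                           as.data.frame(unclass(scores)),
                           stringsAsFactors = FALSE, check.names = FALSE)
    write_stage_tsv(score_df, file.path(out_dir, "ssgsea_scores.tsv"))
    imm <- immune_score(scores)
    anchor_expr <- expr$values[anchor, ]
    cors <- lapply(c(list(immune_score = imm),
                     setNames(lapply(rownames(scores), function(s)
                       scores[s, ]), rownames(scores))),
                   function(v) spearman_exact(anchor_expr, v))
    cor_df <- data.frame(target = names(cors),
                         rho = vapply(cors, `[[`, 0, "rho"),
                         p = vapply(cors, `[[`, 0, "p"),
                         method = vapply(cors, `[[`, "", "method"),
                         stringsAsFactors = FALSE)
    write_stage_tsv(cor_df, file.path(out_dir, "correlations.tsv"))
    related <- related_gene_set(expr, anchor, config$r_min, config$p_max)
    writeLines(related, file.path(out_dir, "related_genes.txt"))

    stage <- "proximity"
    S <- unique(c(anchor, related))
    prox <- run_proximity(g, S, drugs, n_perm = config$n_permutations,
                          seed = config$seed, d_max = config$d_max,
                          fdr_max = config$fdr_max)
    write_stage_tsv(prox, file.path(out_dir, "proximity.tsv"))
    screened <- screen_drugs(prox, config$d_max, config$fdr_max)
    sizes <- unique(prox$n_used[prox$evaluable & prox$n_used > 0])
    dens_null <- null_distribution(g, intersect(S, igraph::V(g)$name),
                                   max(sizes),
                                   n_perm = min(config$n_permutations, 2000),
                                   seed = derive_seed(config$seed,
                                                      "density"))
    write_stage_tsv(proximity_density(prox, dens_null),
                    file.path(out_dir, "distance_density.tsv"))

    stage <- "summary"
    summary <- list(
      seed = config$seed,
      version = as.character(utils::packageVersion("plaquehub")),
      n_genes = nrow(expr$values),
      n_samples = ncol(expr$values),
      n_degs = length(degs),
      n_related_degs = length(related_degs),
      n_enriched_sets = sum(ora$fdr < config$fdr_max),
      n_network_nodes = igraph::vcount(g),
      n_network_edges = igraph::ecount(g),
      n_clusters = length(modules$clusters),
      cluster_scores = modules$scores,
      hub_genes = hubs,
      anchor = anchor,
      loocv_auc = loo_auc$auc_direction_free,
      n_related_genes = length(related),
      n_drugs = length(drugs),
      n_screened_drugs = length(screened),
      screened_drugs = screened,
      config = list(lfc_min = config$lfc_min, fdr_max = config$fdr_max,
                    min_confidence = config$min_confidence,
                    mcode = unclass(config$mcode), r_min = config$r_min,
                    p_max = config$p_max, d_max = config$d_max,
                    n_permutations = config$n_permutations,
                    svm_c = config$svm_c,
                    ssgsea_alpha = config$ssgsea_alpha))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    invisible(summary)
  }, error = on_fail)
}
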