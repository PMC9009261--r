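# Orchestration of the full workflow: merge -> batch correction ->
# tumor/normal regulator tests -> m5C clusters -> immune/ESTIMATE scoring ->
# moderated DEGs -> external-list intersection -> gene clusters -> signature
# partition -> shadow reduction -> m5C score -> survival cutpoint ->
# KM/log-rank per stratification -> optional response and drug-response
# stages. Each stage runs under a derived seed (global seed + stage index)
# and its outputs land in the returned bundle; with `out_dir` set, every
# intermediate is also written as TSV plus a manifest JSON of seeds,
# parameters and filter counts.

stage_seeds <- function(seed) {
  setNames(seed + seq_len(12L) - 1L,
           c("merge", "combat", "regulator_de", "m5c_clusters", "enrichment",
             "deg", "gene_clusters", "partition", "shadow", "score",
             "survival", "drugs"))
}

run_stage <- function(name, enabled, manifest_env, fun) {
  if (!enabled) {
    manifest_env$manifest$stages[[name]] <- "skipped"
    return(NULL)
  }
  out <- tryCatch(fun(), error = function(e) {
    stop2("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
  manifest_env$manifest$stages[[name]] <- "done"
  out
}

#' Run the full m5C scoring workflow
#'
#' @param expression [expr_matrix()] (already merged; use [merge_cohorts()]
#'   first for multiple matrices) with batch and tumor annotations.
#' @param clinical clinical table covering the expression samples.
#' @param immune_sets gene-set collection of immune-cell signatures.
#' @param external_degs character vector: externally derived tumor-vs-normal
#'   DEG list intersected with the cluster DEGs.
#' @param stromal_set,immune_set optional ESTIMATE-style signatures.
#' @param panel_expr,panel_ic50 optional drug-sensitivity training panel.
#' @param regulators clustering feature genes (default the 12 m5C
#'   regulators).
#' @param k_range candidate cluster numbers.
#' @param reps consensus resampling iterations per stratification.
#' @param pItem consensus subsampling fraction.
#' @param deg_alpha adjusted-p cutoff for cluster DEGs (default 0.05).
#' @param adjust multiplicity adjustment (`"bh"` or `"bonferroni"`).
#' @param ssgsea_alpha rank-weight exponent for enrichment scoring.
#' @param minprop minimum group proportion for the survival cutpoint.
#' @param shadow_max_iter shadow-selection iterations per signature block.
#' @param run_batch_correction,run_shadow,run_infiltration,run_response,run_drugs
#'   stage toggles; skipped stages are marked in the manifest and downstream
#'   stages proceed on the untoggled inputs.
#' @param seed global seed, expanded to per-stage seeds by a fixed offset
#'   scheme (recorded in the manifest).
#' @param out_dir optional directory for TSV intermediates and
#'   `manifest.json`.
#' @return List of stage results plus `manifest` (parameters, seeds, filter
#'   counts such as the cluster-DEG and intersected-DEG totals).
#' @export
m5c_pipeline <- function(expression, clinical,
                         immune_sets = NULL, external_degs = NULL,
                         stromal_set = NULL, immune_set = NULL,
                         panel_expr = NULL, panel_ic50 = NULL,
                         regulators = m5c_regulators(),
                         k_range = 2:9, reps = 200, pItem = 0.8,
                         deg_alpha = 0.05, adjust = "bh",
                         ssgsea_alpha = 0.25, minprop = 0.1,
                         shadow_max_iter = 30,
                         run_batch_correction = TRUE, run_shadow = TRUE,
                         run_infiltration = TRUE, run_response = TRUE,
                         run_drugs = TRUE,
                         seed = 1, out_dir = NULL) {
  clinical <- validate_clinical(clinical)
  seeds <- stage_seeds(seed)
  env <- new.env()
  env$manifest <- list(
    parameters = list(k_range = k_range, reps = reps, pItem = pItem,
                      deg_alpha = deg_alpha, adjust = adjust,
                      ssgsea_alpha = ssgsea_alpha, minprop = minprop,
                      shadow_max_iter = shadow_max_iter, seed = seed),
    seeds = as.list(seeds), stages = list(), counts = list())
  res <- list()
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  persist <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }

  info <- sample_info(expression)
  env$manifest$counts$n_samples <- ncol(as_values(expression))
  env$manifest$counts$n_genes_in <- nrow(as_values(expression))

  # --- batch correction -----------------------------------------------
  corrected <- run_stage("combat", run_batch_correction &&
                           length(unique(info$batch)) > 1L, env, function() {
    combat_correct(expression)
  })
  expr_use <- if (is.null(corrected)) expression else corrected$corrected
  res$batch_model <- corrected$model
  persist("expression_corrected.tsv", function(p) write_expression(expr_use, p))

  # --- tumor vs normal regulator tests --------------------------------
  info <- sample_info(expr_use)
  has_normals <- any(!info$tumor, na.rm = TRUE) && any(info$tumor, na.rm = TRUE)
  res$regulator_de <- run_stage("regulator_de", has_normals, env, function() {
    reg <- intersect(regulators, rownames(as_values(expr_use)))
    two_group_test(subset_expr(expr_use, genes = reg),
                   ifelse(info$tumor, "tumor", "normal"), adjust = adjust)
  })

  tumor_ids <- info$sample_id[info$tumor %in% TRUE]
  if (length(tumor_ids) == 0L) tumor_ids <- info$sample_id
  tumor_expr <- subset_expr(expr_use, samples = tumor_ids)
  clin_t <- clinical[match(tumor_ids, clinical$sample_id), , drop = FALSE]
  env$manifest$counts$n_tumor <- length(tumor_ids)

  # --- m5C clusters on regulator expression ---------------------------
  m5c_clusters <- run_stage("m5c_clusters", TRUE, env, function() {
    cluster_stratify(tumor_expr, regulators, label_style = "numeric",
                     k_range = k_range, B = reps, pItem = pItem,
                     seed = seeds[["m5c_clusters"]])
  })
  res$m5c_clusters <- m5c_clusters
  env$manifest$counts$k_m5c <- attr(m5c_clusters, "k")
  env$manifest$counts$m5c_cluster_sizes <- as.list(table(m5c_clusters))
  persist("m5c_clusters.tsv", function(p)
    write.table(data.frame(sample_id = names(m5c_clusters),
                           m5c_cluster = as.vector(m5c_clusters)),
                p, sep = "\t", quote = FALSE, row.names = FALSE))

  # --- immune enrichment / ESTIMATE -----------------------------------
  res$immune_scores <- run_stage("enrichment", !is.null(immune_sets), env, function() {
    ssgsea(tumor_expr, immune_sets, alpha = ssgsea_alpha, normalize = TRUE)
  })
  if (!is.null(res$immune_scores)) {
    res$infiltration <- run_stage("infiltration", run_infiltration, env, function() {
      infiltration_groups(res$immune_scores, n_groups = 3, B = reps,
                          pItem = pItem, seed = seeds[["enrichment"]])
    })
    res$immune_by_cluster <- lapply(colnames(res$immune_scores), function(set)
      group_compare(res$immune_scores[, set], m5c_clusters[rownames(res$immune_scores)]))
    names(res$immune_by_cluster) <- colnames(res$immune_scores)
    persist("immune_scores.tsv", function(p)
      write.table(data.frame(sample_id = rownames(res$immune_scores),
                             res$immune_scores, check.names = FALSE),
                  p, sep = "\t", quote = FALSE, row.names = FALSE))
  }
  res$estimate <- run_stage("estimate",
                            !is.null(stromal_set) && !is.null(immune_set), env,
                            function() {
    estimate_scores(tumor_expr, stromal_set, immune_set)
  })

  # --- moderated DEGs across m5C clusters -----------------------------
  deg_table <- run_stage("deg", TRUE, env, function() {
    moderated_anova(tumor_expr, m5c_clusters[colnames(as_values(tumor_expr))],
                    adjust = adjust)
  })
  res$deg_table <- deg_table
  cluster_degs <- deg_table$gene[deg_table$p_adj < deg_alpha]
  env$manifest$counts$n_genes_tested <- nrow(deg_table)
  env$manifest$counts$n_cluster_degs <- length(cluster_degs)
  persist("cluster_degs.tsv", function(p)
    write.table(deg_table, p, sep = "\t", quote = FALSE, row.names = FALSE))

  # --- intersect with the external tumor-vs-normal DEG list -----------
  m5c_degs <- run_stage("intersect", TRUE, env, function() {
    if (is.null(external_degs)) return(cluster_degs)
    intersect_degs(cluster_degs, external_degs)
  })
  res$m5c_degs <- m5c_degs
  env$manifest$counts$n_external_degs <- length(external_degs %||% character())
  env$manifest$counts$n_m5c_degs <- length(m5c_degs)
  if (length(m5c_degs) < 2L) {
    stop2("pipeline stage 'intersect' failed: fewer than 2 m5C DEGs survive; ",
          "cannot build gene clusters")
  }

  # --- gene clusters on the m5C DEGs ----------------------------------
  gene_clusters <- run_stage("gene_clusters", TRUE, env, function() {
    cluster_stratify(tumor_expr, m5c_degs, label_style = "letter",
                     k_range = k_range, B = reps, pItem = pItem,
                     seed = seeds[["gene_clusters"]])
  })
  res$gene_clusters <- gene_clusters
  env$manifest$counts$k_gene <- attr(gene_clusters, "k")
  env$manifest$counts$gene_cluster_sizes <- as.list(table(gene_clusters))
  persist("gene_clusters.tsv", function(p)
    write.table(data.frame(sample_id = names(gene_clusters),
                           gene_cluster = as.vector(gene_clusters)),
                p, sep = "\t", quote = FALSE, row.names = FALSE))

  # --- signature partition + shadow reduction -------------------------
  deg_expr <- subset_expr(tumor_expr, genes = m5c_degs)
  partition <- run_stage("partition", TRUE, env, function() {
    partition_signatures(deg_expr, gene_clusters, clinical = clin_t)
  })
  partition <- run_stage("shadow", run_shadow, env, function() {
    reduce_signatures(partition, deg_expr, gene_clusters,
                      max_iter = shadow_max_iter, seed = seeds[["shadow"]])
  }) %||% partition
  res$partition <- partition
  env$manifest$counts$n_signature_A <- length(partition$signature_A)
  env$manifest$counts$n_signature_B <- length(partition$signature_B)
  env$manifest$counts$n_retained_A <- length(partition$retained_A %||% partition$signature_A)
  env$manifest$counts$n_retained_B <- length(partition$retained_B %||% partition$signature_B)

  # --- m5C score + cutpoint -------------------------------------------
  score <- run_stage("score", TRUE, env, function() {
    compute_score(deg_expr, partition)
  })
  score <- run_stage("cutpoint", TRUE, env, function() {
    dichotomize(score, clin_t, minprop = minprop)
  })
  res$score <- score
  env$manifest$counts$cutpoint <- attr(score, "cutpoint")
  env$manifest$counts$score_group_sizes <- as.list(table(score$group))
  persist("score.tsv", function(p)
    write.table(score, p, sep = "\t", quote = FALSE, row.names = FALSE))

  # --- survival comparisons -------------------------------------------
  res$survival <- run_stage("survival", TRUE, env, function() {
    idx <- match(score$sample_id, clin_t$sample_id)
    list(
      by_score = km_fit(clin_t$os_time[idx], clin_t$os_event[idx], score$group),
      by_m5c_cluster = km_fit(clin_t$os_time[idx], clin_t$os_event[idx],
                              m5c_clusters[score$sample_id]),
      by_gene_cluster = km_fit(clin_t$os_time[idx], clin_t$os_event[idx],
                               gene_clusters[score$sample_id]))
  })
  env$manifest$counts$logrank_chi2 <- res$survival$by_score$logrank$chi2
  env$manifest$counts$logrank_p <- res$survival$by_score$logrank$p

  # --- immunotherapy response -----------------------------------------
  has_response <- "response" %in% names(clin_t) && any(!is.na(clin_t$response))
  res$response <- run_stage("response", run_response && has_response, env, function() {
    idx <- match(score$sample_id, clin_t$sample_id)
    response_analysis(score$group, clin_t$response[idx], score$m5c_score)
  })

  # --- chemotherapy response ------------------------------------------
  res$drug_response <- run_stage("drugs",
                                 run_drugs && !is.null(panel_expr) && !is.null(panel_ic50),
                                 env, function() {
    pred <- ridge_ic50(panel_expr, panel_ic50, tumor_expr,
                       seed = seeds[["drugs"]])
    comp <- lapply(colnames(pred$predicted), function(drug)
      group_compare(pred$predicted[score$sample_id, drug],
                    score$group))
    names(comp) <- colnames(pred$predicted)
    list(predicted = pred$predicted, lambda = pred$lambda,
         group_comparison = comp,
         differential = names(comp)[vapply(comp, function(x) x$p < 0.05, logical(1))])
  })

  res$manifest <- env$manifest
  if (!is.null(out_dir)) {
    jsonlite::write_json(env$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
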