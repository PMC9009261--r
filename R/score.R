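# The core construction: partition the m5C DEGs into signature A (genes
# positively associated with the gene-cluster ordering) and signature B (the
# rest), prune each block with a shadow-feature (Boruta-style) selector, and
# score each sample as the difference of the two blocks' first principal
# components. The high/low dichotomy is placed at the survival-optimal
# cutpoint (maximally selected log-rank statistic).

#' Partition cluster-associated genes into signatures A and B
#'
#' Gene clusters are encoded as integers ordered by descending mean observed
#' survival time (the cluster with the best outcome gets the highest code),
#' so "positively correlated with gene cluster" aligns with good prognosis
#' and the resulting score increases with survival. Without a clinical
#' table the encoding falls back to reverse-alphabetical cluster order. Per
#' gene, the Spearman correlation between expression and the encoded label
#' decides the side: rho > 0 is signature A, the rest (including constant
#' genes, with a warning) signature B.
#'
#' @param deg_expr [expr_matrix()] or matrix restricted to the m5C DEGs.
#' @param gene_cluster_labels named cluster labels (>= 2 clusters) keyed by
#'   sample ID, as from [cluster_stratify()].
#' @param clinical optional clinical table supplying `os_time` for the
#'   survival-proxy encoding.
#' @return `signature_partition`: `signature_A`, `signature_B`, per-gene
#'   `rho`, the cluster `encoding`, and empty `retained_*` slots filled by
#'   [shadow_select()].
#' @export
partition_signatures <- function(deg_expr, gene_cluster_labels, clinical = NULL) {
  X <- as_values(deg_expr)
  labels <- gene_cluster_labels[colnames(X)]
  if (any(is.na(labels))) stop2("cluster labels missing for some samples")
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop2("need >= 2 gene clusters")

  if (!is.null(clinical)) {
    os <- setNames(clinical$os_time, clinical$sample_id)[colnames(X)]
    mean_os <- tapply(os, labels, mean, na.rm = TRUE)
    ord <- order(mean_os)                       # worst survival first
  } else {
    ord <- order(levels(labels), decreasing = TRUE)
  }
  encoding <- setNames(seq_len(nlevels(labels)), levels(labels)[ord])
  code <- encoding[as.character(labels)]

  rho <- apply(X, 1L, function(x) {
    if (sd(x) == 0) return(NA_real_)
    suppressWarnings(cor(x, code, method = "spearman"))
  })
  if (any(is.na(rho))) {
    warning(sum(is.na(rho)), " constant gene(s) assigned to signature B",
            call. = FALSE)
  }
  a_side <- !is.na(rho) & rho > 0
  structure(list(signature_A = rownames(X)[a_side],
                 signature_B = rownames(X)[!a_side],
                 rho = rho, encoding = encoding,
                 retained_A = NULL, retained_B = NULL,
                 reduction_log = NULL),
            class = "signature_partition")
}

#' @export
print.signature_partition <- function(x, ...) {
  cat("signature_partition: A = ", length(x$signature_A), " genes, B = ",
      length(x$signature_B), " genes\n", sep = "")
  if (!is.null(x$retained_A)) {
    cat("  retained after reduction: A = ", length(x$retained_A), ", B = ",
        length(x$retained_B), "\n", sep = "")
  }
  invisible(x)
}

#' Shadow-feature (Boruta-style) all-relevant feature selection
#'
#' Iteratively augments the feature matrix with "shadow" features (an
#' independently permuted copy of every candidate), fits a random-forest
#' importance estimator, and scores a hit for every real feature whose
#' importance exceeds the maximum shadow importance. After each iteration a
#' two-sided binomial test on the hit count (chance 1/2) is Bonferroni
#' corrected at `fwer_alpha`: features significantly above chance are
#' confirmed, significantly below are rejected and removed. Stops at
#' `max_iter` or when nothing is tentative.
#'
#' @param X samples x features numeric matrix.
#' @param y class labels (e.g. gene-cluster labels), one per sample.
#' @param max_iter maximum iterations (default 100).
#' @param fwer_alpha family-wise error rate for the binomial decisions.
#' @param seed RNG seed.
#' @param keep_tentative include still-tentative features in the returned
#'   selection (default TRUE).
#' @param ntree random-forest trees per iteration.
#' @param importance_fun optional replacement importance estimator,
#'   `function(X, y)` returning one importance per column of `X`.
#' @return List: `selected` (confirmed, plus tentative per flag),
#'   `decision` (per-feature `confirmed`/`rejected`/`tentative`), `hits`,
#'   `iterations`.
#' @export
shadow_select <- function(X, y, max_iter = 100, fwer_alpha = 0.01, seed = NULL,
                          keep_tentative = TRUE, ntree = 300,
                          importance_fun = NULL) {
  if (!is.matrix(X)) X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2L) stop2("need >= 2 classes in y")
  if (ncol(X) < 1L) stop2("need >= 1 feature")
  check_count(max_iter, "max_iter")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))

  imp_fun <- importance_fun %||% function(Xa, ya) {
    fit <- randomForest::randomForest(Xa, ya, ntree = ntree, importance = TRUE)
    randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
  }

  features <- colnames(X)
  decision <- setNames(rep("tentative", length(features)), features)
  hits <- setNames(integer(length(features)), features)
  trials <- 0L

  for (it in seq_len(max_iter)) {
    active <- names(decision)[decision != "rejected"]
    open <- names(decision)[decision == "tentative"]
    if (length(open) == 0L) break
    Xa <- X[, active, drop = FALSE]
    # at least 5 shadows so the max-shadow benchmark stays honest when few
    # candidates remain
    src <- colnames(Xa)[rep_len(seq_along(active), max(5L, length(active)))]
    shadows <- apply(Xa[, src, drop = FALSE], 2L, sample)
    colnames(shadows) <- paste0("shadow_", seq_along(src))
    imp <- tryCatch(imp_fun(cbind(Xa, shadows), y),
                    error = function(e) stop2("importance estimator failed at iteration ",
                                              it, ": ", conditionMessage(e)))
    max_shadow <- max(imp[grepl("^shadow_", names(imp))])
    hit_now <- imp[active] > max_shadow
    hits[active] <- hits[active] + as.integer(hit_now)
    trials <- trials + 1L

    # two-sided binomial decisions, Bonferroni-corrected over all features
    m <- length(features)
    p_up <- pbinom(hits[open] - 1L, trials, 0.5, lower.tail = FALSE)
    p_dn <- pbinom(hits[open], trials, 0.5)
    confirmed <- open[pmin(1, 2 * p_up * m) < fwer_alpha]
    rejected <- open[pmin(1, 2 * p_dn * m) < fwer_alpha]
    decision[confirmed] <- "confirmed"
    decision[rejected] <- "rejected"
  }
  selected <- names(decision)[decision == "confirmed" |
                                (keep_tentative & decision == "tentative")]
  list(selected = selected, decision = decision, hits = hits,
       iterations = trials)
}

#' Reduce both signatures with the shadow selector
#'
#' Runs [shadow_select()] separately within signature A and signature B with
#' the gene-cluster labels as target and records the retained sets in the
#' partition. A block whose selection comes back empty keeps its full gene
#' list (with a warning) so the score stays defined.
#'
#' @param partition a [partition_signatures()] result.
#' @param deg_expr the expression matrix the partition was built from.
#' @param gene_cluster_labels the clustering target.
#' @inheritParams shadow_select
#' @return The partition with `retained_A`, `retained_B`, `reduction_log`
#'   filled in.
#' @export
reduce_signatures <- function(partition, deg_expr, gene_cluster_labels,
                              max_iter = 30, fwer_alpha = 0.01, seed = NULL,
                              keep_tentative = TRUE, ntree = 300) {
  stopifnot(inherits(partition, "signature_partition"))
  X <- t(as_values(deg_expr))
  y <- gene_cluster_labels[rownames(X)]
  run_block <- function(genes, block_seed) {
    if (length(genes) < 2L) {
      return(list(selected = genes, decision = setNames(rep("confirmed", length(genes)), genes),
                  hits = NULL, iterations = 0L))
    }
    shadow_select(X[, genes, drop = FALSE], y, max_iter = max_iter,
                  fwer_alpha = fwer_alpha, seed = block_seed,
                  keep_tentative = keep_tentative, ntree = ntree)
  }
  resA <- run_block(partition$signature_A, seed)
  resB <- run_block(partition$signature_B, if (is.null(seed)) NULL else seed + 1L)
  keep_or_all <- function(selected, all, side) {
    if (length(selected) == 0L && length(all) > 0L) {
      warning("shadow selection emptied signature ", side,
              "; keeping the full block", call. = FALSE)
      return(all)
    }
    selected
  }
  partition$retained_A <- keep_or_all(resA$selected, partition$signature_A, "A")
  partition$retained_B <- keep_or_all(resB$selected, partition$signature_B, "B")
  partition$reduction_log <- list(A = resA, B = resB)
  partition
}

#' Compute the per-sample m5C score
#'
#' `score_i = PC1A_i - PC1B_i`, where PC1A/PC1B are the first principal
#' components of the z-scored expression of the retained signature A and B
#' genes (loading-sum-positive orientation, see [pca_first_component()]).
#' An empty signature B contributes PC1B = 0; an empty A is an error.
#'
#' @param expr [expr_matrix()] or matrix covering the signature genes.
#' @param partition a [partition_signatures()] result; the `retained_*`
#'   slots are used when present, otherwise the full signatures.
#' @return `score_result` data.frame: `sample_id`, `pc1a`, `pc1b`,
#'   `m5c_score` (+ `cutpoint`/`group` after [dichotomize()]).
#' @export
compute_score <- function(expr, partition) {
  stopifnot(inherits(partition, "signature_partition"))
  X <- as_values(expr)
  genes_A <- partition$retained_A %||% partition$signature_A
  genes_B <- partition$retained_B %||% partition$signature_B
  genes_A <- intersect(genes_A, rownames(X))
  genes_B <- intersect(genes_B, rownames(X))
  if (length(genes_A) == 0L) stop2("signature A is empty; score undefined")
  pc_a <- pca_first_component(t(X[genes_A, , drop = FALSE]))
  pc1a <- pc_a$projection
  if (length(genes_B) > 0L) {
    pc_b <- pca_first_component(t(X[genes_B, , drop = FALSE]))
    pc1b <- pc_b$projection
  } else {
    pc_b <- NULL
    pc1b <- setNames(rep(0, ncol(X)), colnames(X))
  }
  out <- data.frame(sample_id = colnames(X), pc1a = unname(pc1a),
                    pc1b = unname(pc1b),
                    m5c_score = unname(pc1a - pc1b),
                    stringsAsFactors = FALSE)
  attr(out, "loadings") <- list(A = pc_a$loadings,
                                B = if (is.null(pc_b)) NULL else pc_b$loadings)
  class(out) <- c("score_result", "data.frame")
  out
}

# Standardized two-group log-rank statistic (O - E) / sqrt(V) for a logical
# split; the building block of the maximally selected cutpoint.
logrank_z <- function(times, events, in_high) {
  ev_times <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    N_t <- sum(at_risk)
    if (N_t < 2) next
    d_t <- sum(times == t & events == 1)
    n1 <- sum(at_risk & in_high)
    O <- O + sum(times == t & events == 1 & in_high)
    E <- E + d_t * n1 / N_t
    V <- V + d_t * (n1 / N_t) * (1 - n1 / N_t) * (N_t - d_t) / (N_t - 1)
  }
  if (V <= 0) return(0)
  (O - E) / sqrt(V)
}

#' Dichotomize scores at the survival-optimal cutpoint
#'
#' Maximally selected log-rank statistic: every observed score value leaving
#' at least `ceiling(minprop * n)` samples on each side is a candidate
#' cutpoint; the one maximizing the absolute standardized two-group log-rank
#' statistic wins (ties go to the lower cutpoint). Groups are `high`
#' (score > cutpoint) and `low` (score <= cutpoint).
#'
#' @param score a [compute_score()] result.
#' @param clinical clinical table with `os_time`/`os_event` covering every
#'   scored sample.
#' @param minprop minimum group proportion (default 0.1).
#' @return The score data.frame with `group` filled in and attributes
#'   `cutpoint` and `cutpoint_statistic`.
#' @export
dichotomize <- function(score, clinical, minprop = 0.1) {
  stopifnot(inherits(score, "score_result"))
  check_number(minprop, "minprop", min = 0, max = 0.5)
  idx <- match(score$sample_id, clinical$sample_id)
  if (any(is.na(idx))) stop2("survival information missing for some scored samples")
  times <- clinical$os_time[idx]
  events <- clinical$os_event[idx]
  if (any(is.na(times)) || any(is.na(events))) stop2("missing os_time/os_event")
  s <- score$m5c_score
  n <- length(s)
  min_side <- ceiling(minprop * n)
  sorted <- sort(unique(s))
  candidates <- sorted[vapply(sorted, function(c)
    sum(s <= c) >= min_side && sum(s > c) >= min_side, logical(1))]
  if (length(candidates) < 1L) stop2("no valid cutpoint candidates at minprop = ", minprop)
  zs <- vapply(candidates, function(c) logrank_z(times, events, s > c), numeric(1))
  best <- which.max(abs(zs))          # first max = lowest cutpoint on ties
  cut <- candidates[best]
  score$group <- ifelse(s > cut, "high", "low")
  score$cutpoint <- cut
  attr(score, "cutpoint") <- cut
  attr(score, "cutpoint_statistic") <- zs[best]
  score
}
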