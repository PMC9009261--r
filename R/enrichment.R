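# Single-sample gene-set enrichment (ssGSEA) and the ESTIMATE-style
# stromal/immune composite. The per-sample enrichment statistic is the
# integrated difference between the weighted in-set and unweighted
# out-of-set empirical CDFs along the expression-ranked gene list:
# walking down the list sorted by descending expression,
#   P_in(i)  = sum_{j in S, pos(j) <= i} r_j^alpha / sum_{j in S} r_j^alpha
#   P_out(i) = #{j not in S, pos(j) <= i} / (N - |S|)
#   ES       = sum_i (P_in(i) - P_out(i))
# with r_j the (ascending, mid-rank) rank of gene j, so the top gene
# carries weight N^alpha. Rank-based, hence invariant to any strictly
# increasing per-sample transform of expression.

#' Single-sample gene-set enrichment scores
#'
#' @param expr [expr_matrix()] or genes x samples matrix.
#' @param sets [gene_set_collection()] or named list of gene vectors. Genes
#'   absent from the matrix are filtered out (and reported via the
#'   `absent_genes` attribute); a set left empty after filtering, or a set
#'   covering every gene, is an error.
#' @param alpha rank-weight exponent (default 0.25).
#' @param normalize divide the whole score matrix by its range
#'   (max ES - min ES), the usual normalization for cross-set comparison.
#' @return samples x sets numeric matrix of enrichment scores.
#' @export
ssgsea <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  X <- as_values(expr)
  genes <- rownames(X)
  N <- nrow(X)
  sets <- as.list(sets)
  if (is.null(names(sets))) stop2("gene sets must be named")
  filtered <- lapply(sets, function(s) unique(intersect(s, genes)))
  absent <- mapply(function(s, f) setdiff(unique(s), f), sets, filtered,
                   SIMPLIFY = FALSE)
  empty <- lengths(filtered) == 0L
  if (any(empty)) stop2("gene set(s) empty after filtering: ",
                        paste(names(sets)[empty], collapse = ", "))
  full <- lengths(filtered) >= N
  if (any(full)) stop2("gene set(s) cover all genes (out-of-set CDF undefined): ",
                       paste(names(sets)[full], collapse = ", "))

  member <- lapply(filtered, function(s) genes %in% s)
  ES <- matrix(0, ncol(X), length(sets),
               dimnames = list(colnames(X), names(sets)))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    r <- rank(x, ties.method = "average")
    ord <- order(-x, genes)                 # ties broken by gene ID for
    w_all <- r[ord]^alpha                   # order-invariance of the input
    for (s in seq_along(filtered)) {
      inset <- member[[s]][ord]
      w_in <- w_all * inset
      P_in <- cumsum(w_in) / sum(w_in)
      P_out <- cumsum(!inset) / (N - sum(inset))
      ES[j, s] <- sum(P_in - P_out)
    }
  }
  if (normalize) {
    rng <- max(ES) - min(ES)
    if (rng > 0) ES <- ES / rng
  }
  attr(ES, "alpha") <- alpha
  attr(ES, "normalized") <- normalize
  attr(ES, "absent_genes") <- absent
  ES
}

#' Assign infiltration-level groups from immune enrichment scores
#'
#' Consensus-clusters the samples on their immune-cell enrichment score
#' matrix at `k = n_groups` and names the groups by descending mean total
#' score: `high`, `moderate`, `low` for three groups (`high`/`low` for two;
#' `group<i>` beyond three).
#'
#' @param scores samples x sets matrix from [ssgsea()].
#' @param n_groups number of infiltration tiers (default 3).
#' @inheritParams consensus_cluster
#' @return Named character vector of group labels keyed by sample ID.
#' @export
infiltration_groups <- function(scores, n_groups = 3, B = 200, pItem = 0.8,
                                seed = NULL) {
  check_count(n_groups, "n_groups")
  if (nrow(scores) < n_groups) stop2("fewer samples than groups")
  if (n_groups == 1L) {
    return(setNames(rep("high", nrow(scores)), rownames(scores)))
  }
  if (sd(as.vector(scores)) == 0) stop2("degenerate constant score matrix")
  res <- consensus_cluster(t(scores), k_range = n_groups, B = B, pItem = pItem,
                           seed = seed)
  raw <- res$labels[[as.character(n_groups)]]
  mean_by_cluster <- tapply(rowMeans(scores), raw, mean)
  ord <- order(mean_by_cluster, decreasing = TRUE)
  tier_names <- switch(as.character(n_groups),
                       "2" = c("high", "low"),
                       "3" = c("high", "moderate", "low"),
                       paste0("group", seq_len(n_groups)))
  map <- setNames(tier_names, names(mean_by_cluster)[ord])
  setNames(unname(map[as.character(raw)]), names(raw))
}

# Published calibration constants of the purity transform.
ESTIMATE_PURITY_A <- 0.6049872018
ESTIMATE_PURITY_B <- 0.0001467884

#' ESTIMATE-style stromal/immune composite scores and tumor purity
#'
#' Stromal and immune scores are unnormalized [ssgsea()] enrichment scores
#' (alpha = 0.25) of the two signatures; the ESTIMATE score is their sum and
#' tumor purity is `cos(0.6049872018 + 0.0001467884 * ESTIMATE)`, applied
#' verbatim from its published calibration. Purity is reported only while
#' the cosine argument stays in \[0, pi\]; samples outside that band are
#' flagged `out_of_calibration` (the transform is platform-calibrated).
#'
#' @param expr [expr_matrix()] or matrix.
#' @param stromal_set,immune_set character gene vectors.
#' @return data.frame per sample: `stromal_score`, `immune_score`,
#'   `estimate_score`, `purity` (NA when flagged), `out_of_calibration`.
#' @export
estimate_scores <- function(expr, stromal_set, immune_set) {
  es <- ssgsea(expr, list(stromal = stromal_set, immune = immune_set),
               alpha = 0.25, normalize = FALSE)
  estimate <- es[, "stromal"] + es[, "immune"]
  arg <- ESTIMATE_PURITY_A + ESTIMATE_PURITY_B * estimate
  ok <- arg >= 0 & arg <= pi
  purity <- ifelse(ok, cos(arg), NA_real_)
  data.frame(sample_id = rownames(es),
             stromal_score = es[, "stromal"], immune_score = es[, "immune"],
             estimate_score = estimate, purity = purity,
             out_of_calibration = !ok,
             stringsAsFactors = FALSE, row.names = NULL)
}
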