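# Resampling-based consensus clustering with stability-driven selection of
# the number of clusters, plus the shared first-principal-component utility.
# For each candidate k, B subsamples of ceil(pItem * n) samples are
# clustered (k-means by default; average-linkage hierarchical optional) and
# the consensus matrix M[i, j] = (#times co-clustered) / (#times
# co-sampled) is accumulated. Final labels cut an average-linkage tree of
# 1 - M at k. Stability is summarized per k by the PAC (proportion of
# ambiguous consensus entries in (0.1, 0.9)) and by the relative increase
# in the area under the consensus CDF.

# k-means++ seeding: spread the k initial centers by sampling points with
# probability proportional to squared distance from the nearest chosen
# center. Makes single-start k-means stable enough for consensus resampling.
kmeanspp_centers <- function(D, k) {
  n <- nrow(D)
  ctr <- integer(k)
  ctr[1] <- sample.int(n, 1L)
  d2 <- colSums((t(D) - D[ctr[1], ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) {
      cand <- setdiff(seq_len(n), ctr[seq_len(j - 1L)])
      ctr[j] <- cand[1]
    } else {
      ctr[j] <- sample.int(n, 1L, prob = d2 / sum(d2))
    }
    d2 <- pmin(d2, colSums((t(D) - D[ctr[j], ])^2))
  }
  D[ctr, , drop = FALSE]
}

inner_partition <- function(Db, k, inner, nstart = 3L) {
  if (inner == "kmeans") {
    best <- NULL
    for (s in seq_len(nstart)) {
      fit <- tryCatch(kmeans(Db, centers = kmeanspp_centers(Db, k), iter.max = 30),
                      error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
        best <- fit
      }
    }
    if (!is.null(best)) return(best$cluster)
  }
  cutree(hclust(dist(Db), method = "average"), k = k)
}

#' Consensus clustering of samples by resampling
#'
#' @param expr [expr_matrix()] or genes x samples matrix, already restricted
#'   to the feature set of interest. Features are z-scored per gene before
#'   clustering.
#' @param k_range candidate cluster numbers (default 2:9).
#' @param B resampling iterations (default 1000).
#' @param pItem fraction of samples drawn (without replacement) per
#'   iteration, in (0, 1].
#' @param inner inner clustering algorithm: `"kmeans"` (default) or
#'   `"hclust"` (Euclidean, average linkage).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return `consensus_result`: per-k consensus matrices, final labels, PAC,
#'   CDF areas and delta-area statistics, plus the resampling settings. The
#'   per-k element `never_cosampled` counts sample pairs that were never
#'   drawn together (their consensus is set to 0).
#' @export
consensus_cluster <- function(expr, k_range = 2:9, B = 1000, pItem = 0.8,
                              inner = c("kmeans", "hclust"), seed = NULL) {
  inner <- match.arg(inner)
  if (!is.numeric(pItem) || pItem <= 0 || pItem > 1) stop2("pItem must lie in (0, 1]")
  check_count(B, "B")
  X <- as_values(expr)
  X <- zscore_rows(X)
  D <- t(X)                                   # samples x features
  n <- nrow(D)
  if (n < max(k_range) + 1L) stop2("need at least max(k_range) + 1 samples")
  if (!is.null(seed)) set.seed(seed)
  n_sub <- ceiling(pItem * n)

  result <- list(k_range = k_range, B = B, pItem = pItem, inner = inner,
                 seed = seed, M = list(), labels = list(), pac = numeric(0),
                 cdf_area = numeric(0), delta_area = numeric(0),
                 never_cosampled = integer(0))
  samp_count <- matrix(0, n, n)
  subsamples <- lapply(seq_len(B), function(b) sort(sample.int(n, n_sub)))
  for (idx in subsamples) samp_count[idx, idx] <- samp_count[idx, idx] + 1

  for (k in k_range) {
    conn <- matrix(0, n, n)
    for (idx in subsamples) {
      Db <- D[idx, , drop = FALSE]
      cl <- inner_partition(Db, k, inner)
      for (c in unique(cl)) {
        mem <- idx[cl == c]
        conn[mem, mem] <- conn[mem, mem] + 1
      }
    }
    M <- ifelse(samp_count > 0, conn / pmax(samp_count, 1), 0)
    dimnames(M) <- list(rownames(D), rownames(D))
    labels <- cutree(hclust(as.dist(1 - M), method = "average"), k = k)
    names(labels) <- rownames(D)
    upper <- M[upper.tri(M)]
    kc <- as.character(k)
    result$M[[kc]] <- M
    result$labels[[kc]] <- labels
    result$pac[kc] <- mean(upper > 0.1 & upper < 0.9)
    sv <- sort(upper)
    cdf <- seq_along(sv) / length(sv)
    result$cdf_area[kc] <- sum(diff(sv) * cdf[-length(cdf)])
    result$never_cosampled[kc] <- sum(samp_count[upper.tri(samp_count)] == 0)
  }
  a <- result$cdf_area
  result$delta_area <- c(a[1], diff(a) / a[-length(a)])
  names(result$delta_area) <- names(a)
  class(result) <- "consensus_result"
  result
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result over k = {", paste(x$k_range, collapse = ", "),
      "}, B = ", x$B, ", pItem = ", x$pItem, "\n", sep = "")
  print(round(rbind(PAC = x$pac, delta_area = x$delta_area), 3))
  invisible(x)
}

#' Select the number of clusters from a consensus result
#'
#' `"delta_area"` (default) picks the largest k whose relative increase in
#' the area under the consensus CDF exceeds 0.1 -- the classical elbow
#' criterion. `"pac"` picks the k minimizing the proportion of ambiguous
#' consensus entries (ties broken toward the smallest k); note that on
#' cleanly nested structure PAC can be exactly zero for every k up to the
#' true one, in which case its smallest-k tie-break under-estimates k --
#' hence the elbow default. When even the best PAC exceeds 0.25 the choice
#' is flagged low-confidence (`attr(k, "low_confidence")`), as happens on
#' structureless data.
#'
#' @param result a [consensus_cluster()] result.
#' @param method `"delta_area"` or `"pac"`.
#' @return The chosen k (integer) with a `low_confidence` attribute.
#' @export
select_k <- function(result, method = c("delta_area", "pac")) {
  method <- match.arg(method)
  stopifnot(inherits(result, "consensus_result"))
  ks <- result$k_range
  if (length(ks) == 1L) {
    k <- ks
    attr(k, "low_confidence") <- unname(result$pac[1] > 0.25)
    return(k)
  }
  if (method == "pac") {
    k <- ks[which.min(result$pac)]
    low <- min(result$pac) > 0.25
  } else {
    ok <- which(result$delta_area > 0.1)
    k <- if (length(ok)) ks[max(ok)] else ks[1]
    low <- min(result$pac) > 0.25
  }
  if (low) warning("no clear cluster structure: minimum PAC = ",
                   round(min(result$pac), 3), call. = FALSE)
  attr(k, "low_confidence") <- unname(low)
  k
}

#' Cluster samples on a feature gene set and name clusters by expression
#'
#' Convenience wrapper: restrict to the feature set, consensus-cluster,
#' select k (unless `k` is given), and name clusters by descending mean
#' feature expression -- cluster `1` (or `A`) has the highest mean z-scored
#' feature expression.
#'
#' @param expr [expr_matrix()] or matrix.
#' @param feature_set character vector of gene IDs (intersection with the
#'   matrix must be non-empty).
#' @param label_style `"numeric"` (1, 2, ...) or `"letter"` (A, B, ...).
#' @param k fix the number of clusters instead of selecting it.
#' @inheritParams consensus_cluster
#' @return Named character vector of cluster labels keyed by sample ID, with
#'   attributes `k` and `consensus` (the full result).
#' @export
cluster_stratify <- function(expr, feature_set, label_style = c("numeric", "letter"),
                             k = NULL, k_range = 2:9, B = 1000, pItem = 0.8,
                             inner = "kmeans", seed = NULL,
                             select_method = c("delta_area", "pac")) {
  label_style <- match.arg(label_style)
  select_method <- match.arg(select_method)
  X <- as_values(expr)
  feats <- intersect(feature_set, rownames(X))
  if (length(feats) == 0L) stop2("feature set shares no genes with the matrix")
  sub <- X[feats, , drop = FALSE]
  res <- consensus_cluster(sub, k_range = if (is.null(k)) k_range else k,
                           B = B, pItem = pItem, inner = inner, seed = seed)
  k_sel <- if (is.null(k)) select_k(res, method = select_method) else k
  raw <- res$labels[[as.character(k_sel)]]
  # name by descending mean z-scored feature expression
  Z <- zscore_rows(sub, na_action = "drop")
  mean_by_cluster <- tapply(colMeans(Z), raw, mean)
  ord <- order(mean_by_cluster, decreasing = TRUE)
  new_names <- if (label_style == "letter") LETTERS[seq_along(ord)] else as.character(seq_along(ord))
  map <- setNames(new_names, names(mean_by_cluster)[ord])
  labels <- setNames(unname(map[as.character(raw)]), names(raw))
  attr(labels, "k") <- as.integer(k_sel)
  attr(labels, "consensus") <- res
  labels
}

#' First principal component of a samples x genes submatrix
#'
#' Genes are z-scored; the component sign is oriented so the sum of gene
#' loadings is positive, making the projection increase with overall
#' signature expression (a platform-stable sign convention).
#'
#' @param X samples x genes numeric matrix (>= 2 samples, >= 1 gene).
#' @return List: `projection` (named per-sample scores, mean 0) and
#'   `loadings` (named per-gene weights, unit norm).
#' @export
pca_first_component <- function(X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) < 2L) stop2("need >= 2 samples")
  s <- apply(X, 2L, sd)
  if (all(s == 0)) stop2("zero-variance submatrix")
  if (any(s == 0)) {
    X <- X[, s > 0, drop = FALSE]
    s <- s[s > 0]
  }
  Z <- scale(X)
  sv <- svd(Z, nu = 1, nv = 1)
  loadings <- drop(sv$v)
  if (sum(loadings) < 0) loadings <- -loadings
  proj <- drop(Z %*% loadings)
  names(proj) <- rownames(X)
  names(loadings) <- colnames(X)
  list(projection = proj, loadings = loadings)
}
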