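# Differential expression: two-group tumor/normal tests (Student t or
# Wilcoxon, with an automatic normality gate), a moderated one-way F test
# across >= 2 clusters with empirical-Bayes variance shrinkage, multiplicity
# adjustment and DEG-list intersection.

#' Two-group differential expression per gene
#'
#' @param expr [expr_matrix()] or genes x samples matrix.
#' @param groups binary grouping (factor/character/logical), one per sample.
#' @param method `"t"` (Student, equal variances), `"wilcoxon"`, or `"auto"`
#'   (Shapiro-Wilk at alpha = 0.05 within each group per gene; any
#'   non-normal group routes the gene to Wilcoxon).
#' @param adjust multiplicity adjustment for the `p_adj` column.
#' @return `data.frame`, one row per gene: group means, `logfc` (mean of the
#'   second group level minus the first, on log scale), `statistic`, `p`,
#'   `p_adj`, `method`.
#' @export
two_group_test <- function(expr, groups, method = c("auto", "t", "wilcoxon"),
                           adjust = "bh") {
  method <- match.arg(method)
  X <- as_values(expr)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop2("exactly 2 groups required")
  if (any(table(groups) < 2L)) stop2("both groups need >= 2 samples")
  g1 <- which(groups == levels(groups)[1])
  g2 <- which(groups == levels(groups)[2])

  one_gene <- function(x) {
    x1 <- x[g1]; x2 <- x[g2]
    m1 <- mean(x1); m2 <- mean(x2)
    use <- method
    if (use == "auto") {
      normal <- function(v) {
        if (length(unique(v)) < 3L) return(FALSE)
        shapiro.test(v)$p.value >= 0.05
      }
      use <- if (normal(x1) && normal(x2)) "t" else "wilcoxon"
    }
    if (sd(c(x1, x2)) == 0) {
      return(c(m1, m2, 0, if (use == "t") 0 else length(x1) * length(x2) / 2, 1, use == "t"))
    }
    if (use == "t") {
      tt <- t.test(x2, x1, var.equal = TRUE)
      c(m1, m2, m2 - m1, unname(tt$statistic), tt$p.value, 1)
    } else {
      wt <- suppressWarnings(wilcox.test(x2, x1))
      c(m1, m2, m2 - m1, unname(wt$statistic), wt$p.value, 0)
    }
  }
  res <- t(apply(X, 1L, one_gene))
  out <- data.frame(gene = rownames(X),
                    mean_1 = res[, 1], mean_2 = res[, 2], logfc = res[, 3],
                    statistic = res[, 4], p = res[, 5],
                    method = ifelse(res[, 6] == 1, "t", "wilcoxon"),
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("mean_", levels(groups))
  out$p_adj <- adjust_p(out$p, adjust)
  rownames(out) <- NULL
  out
}

# Invert the trigamma function by Newton iteration (for the prior-df
# moment-matching step).
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  y <- 0.5 + 1 / x
  for (i in seq_len(50)) {
    tri <- trigamma(y)
    dif <- (tri - x) / psigamma(y, 2)
    y <- y - dif
    if (y <= 0) y <- 1e-8
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Moderated one-way F test across clusters
#'
#' Per gene, a one-way linear model over `cluster_labels`. The residual
#' variance is shrunk toward a common prior by empirical Bayes: the prior
#' degrees of freedom `d0` and prior variance `s0^2` are estimated by
#' matching the moments of `log(s_g^2)` across genes (digamma/trigamma
#' identities for the log of a scaled chi-square); the posterior variance is
#' `(d0 * s0^2 + d * s_g^2) / (d0 + d)` and the moderated F statistic is the
#' between-group mean square over it, on (k - 1, d0 + d) degrees of freedom.
#' When the trigamma equation has no solution, `d0 = Inf` (complete
#' shrinkage) with a warning.
#'
#' @param expr [expr_matrix()] or genes x samples matrix.
#' @param cluster_labels grouping with >= 2 levels, each with >= 2 samples.
#' @param prior_df force `d0` instead of estimating it (`0` recovers the
#'   classical ANOVA F; `Inf` uses the common prior variance alone).
#' @param adjust multiplicity adjustment for `p_adj`.
#' @return `data.frame`: per-gene group means, `logfc` (largest pairwise
#'   group-mean difference), `s2` (residual variance), `F` (moderated), `p`,
#'   `p_adj`, plus attributes `d0` and `s02`.
#' @export
moderated_anova <- function(expr, cluster_labels, prior_df = NULL, adjust = "bh") {
  X <- as_values(expr)
  groups <- factor(cluster_labels)
  k <- nlevels(groups)
  if (k < 2L) stop2("need >= 2 groups")
  if (any(table(groups) < 2L)) stop2("every group needs >= 2 samples")
  n <- ncol(X)
  d <- n - k
  if (d <= 0L) stop2("zero residual degrees of freedom")

  idx <- split(seq_len(n), groups)
  n_j <- lengths(idx)
  means <- vapply(idx, function(ix) rowMeans(X[, ix, drop = FALSE]), numeric(nrow(X)))
  grand <- rowMeans(X)
  ssb <- drop((means - grand)^2 %*% n_j)
  msb <- ssb / (k - 1)
  fitted <- means[, as.integer(groups), drop = FALSE]
  ssw <- rowSums((X - fitted)^2)
  s2 <- ssw / d

  if (is.null(prior_df)) {
    zl <- log(s2)
    if (any(!is.finite(zl))) stop2("zero residual variance for gene(s): ",
                                   paste(head(rownames(X)[!is.finite(zl)], 5), collapse = ", "))
    vz <- var(zl)
    excess <- vz - trigamma(d / 2)
    if (vz < 1e-12) {
      # all residual variances numerically identical: point-mass prior at
      # the common value, so the moderated F equals the classical F
      warning("identical residual variances; using complete shrinkage (d0 = Inf)",
              call. = FALSE)
      d0 <- Inf
      s02 <- exp(mean(zl))
    } else if (is.na(excess) || excess <= 0) {
      warning("no finite prior df solution; using complete shrinkage (d0 = Inf)",
              call. = FALSE)
      d0 <- Inf
      s02 <- exp(mean(zl) - digamma(d / 2) + log(d / 2))
    } else {
      d0 <- 2 * trigamma_inverse(excess)
      s02 <- exp(mean(zl) - digamma(d / 2) + log(d / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
    }
  } else {
    d0 <- prior_df
    s02 <- if (d0 == 0) 0 else exp(mean(log(s2)) - digamma(d / 2) + log(d / 2))
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else (d0 * s02 + d * s2) / (d0 + d)
  Fmod <- msb / s2_post
  df2 <- min(d0 + d, 1e7)
  p <- pf(Fmod, k - 1, df2, lower.tail = FALSE)

  logfc <- apply(means, 1L, function(m) max(m) - min(m))
  out <- data.frame(gene = rownames(X), means, logfc = logfc, s2 = s2,
                    F = Fmod, p = p, p_adj = adjust_p(p, adjust),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[2:(1 + k)] <- paste0("mean_", levels(groups))
  rownames(out) <- NULL
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

#' Multiplicity adjustment
#'
#' Thin validated wrapper over the standard step-up Benjamini-Hochberg and
#' Bonferroni adjustments.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param method `"bh"` or `"bonferroni"`.
#' @return Adjusted p-values (same length and order).
#' @export
adjust_p <- function(p_values, method = c("bh", "bonferroni")) {
  method <- match.arg(tolower(method), c("bh", "bonferroni"))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop2("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = if (method == "bh") "BH" else "bonferroni")
}

#' Intersect cluster DEGs with an external DEG list
#'
#' Set intersection preserving the cluster-DEG ordering; the counts of both
#' inputs and the intersection are attached as the `counts` attribute. An
#' empty intersection is a warning, not an error.
#'
#' @param cluster_degs character vector (e.g. genes at adjusted p < 0.05
#'   across clusters).
#' @param external_degs character vector (e.g. a tumor-vs-normal DEG list).
#' @return Character vector of shared genes.
#' @export
intersect_degs <- function(cluster_degs, external_degs) {
  if (length(cluster_degs) == 0L || length(external_degs) == 0L) {
    stop2("both DEG lists must be nonempty")
  }
  out <- cluster_degs[cluster_degs %in% external_degs]
  if (length(out) == 0L) {
    warning("empty DEG intersection; downstream signature construction will halt",
            call. = FALSE)
  }
  attr(out, "counts") <- c(cluster = length(unique(cluster_degs)),
                           external = length(unique(external_degs)),
                           intersection = length(unique(out)))
  out
}
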