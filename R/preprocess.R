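# Cohort merging and parametric empirical-Bayes batch correction.
# The correction follows the classical location/scale model for
# log-expression: x_gij = alpha_g + gamma_bg + delta_bg * eps_gij. Per-gene
# batch location and scale estimates are shrunk across genes within each
# batch (normal prior on location, inverse-gamma on scale, hyperparameters
# by method of moments) and the adjusted value maps each batch back onto the
# pooled location/scale. Variances use maximum-likelihood denominators
# (n for the pooled variance, n_b per batch), which makes the correction an
# exact no-op when batches are literally identical.

#' Merge expression cohorts on their shared genes
#'
#' Gene set = intersection across inputs; samples are concatenated and keep
#' their batch annotation (or get `cohort<i>`). The returned merge report
#' (`attr(x, "merge_report")`) lists the genes each cohort contributed that
#' did not survive the intersection.
#'
#' @param matrices list of [expr_matrix()] objects (or bare matrices).
#' @return Merged [expr_matrix()] with a `merge_report` attribute.
#' @export
merge_cohorts <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 1L) stop2("need >= 1 matrix")
  if (length(matrices) == 1L) {
    out <- matrices[[1]]
    if (!inherits(out, "m5c_expr")) out <- expr_matrix(as_values(out))
    attr(out, "merge_report") <- list(n_cohorts = 1L,
                                      genes_kept = nrow(as_values(out)),
                                      genes_lost = list())
    return(out)
  }
  gene_lists <- lapply(matrices, function(m) rownames(as_values(m)))
  shared <- Reduce(intersect, gene_lists)
  if (length(shared) == 0L) stop2("empty gene intersection across cohorts")
  lost <- lapply(gene_lists, function(g) setdiff(g, shared))
  names(lost) <- paste0("cohort", seq_along(matrices))
  values <- do.call(cbind, lapply(matrices, function(m) as_values(m)[shared, , drop = FALSE]))
  batch <- unlist(lapply(seq_along(matrices), function(i) {
    info <- sample_info(matrices[[i]])
    b <- info$batch
    b[is.na(b)] <- paste0("cohort", i)
    b
  }))
  tumor <- unlist(lapply(matrices, function(m) sample_info(m)$tumor))
  if (anyDuplicated(colnames(values))) stop2("duplicate sample IDs across cohorts")
  out <- expr_matrix(values, batch = batch, tumor = tumor)
  attr(out, "merge_report") <- list(n_cohorts = length(matrices),
                                    genes_kept = length(shared),
                                    genes_lost = lost)
  out
}

#' Empirical-Bayes batch correction (parametric, ComBat-style)
#'
#' Standardizes each gene against its batch-design fit, estimates per-batch
#' per-gene location (`gamma`) and scale (`delta^2`) effects, shrinks them
#' across genes within each batch via a parametric empirical-Bayes step
#' (normal prior on location, inverse-gamma on scale; hyperparameters by
#' method of moments), and back-transforms. Genes constant within any batch
#' are dropped with a warning (their scale effect is undefined); genes
#' constant overall are an error.
#'
#' @param expr an [expr_matrix()] with >= 2 batches, each with >= 2 samples
#'   (or a bare matrix plus `batch`).
#' @param batch optional batch labels overriding the annotation.
#' @return List: `corrected` ([expr_matrix()], same shape and IDs up to any
#'   dropped degenerate genes) and `model` (per-batch raw and shrunk
#'   location/scale estimates plus hyperparameters).
#' @export
combat_correct <- function(expr, batch = NULL) {
  X <- as_values(expr)
  info <- sample_info(expr)
  batch <- batch %||% info$batch
  if (any(is.na(batch))) stop2("batch annotation required for every sample")
  batch <- factor(batch)
  nb <- nlevels(batch)
  if (nb < 2L) stop2("need >= 2 batches")
  n_b <- as.vector(table(batch))
  if (any(n_b < 2L)) {
    stop2("batch(es) with a single sample (scale inestimable): ",
          paste(levels(batch)[n_b < 2L], collapse = ", "))
  }
  n <- ncol(X)

  # per-batch means and the batch-design grand mean
  bm <- vapply(levels(batch), function(b) rowMeans(X[, batch == b, drop = FALSE]),
               numeric(nrow(X)))
  alpha <- drop(bm %*% (n_b / n))
  resid <- X - bm[, as.integer(batch), drop = FALSE]
  var_pooled <- rowMeans(resid^2)
  if (any(var_pooled == 0)) {
    stop2("constant gene(s): ",
          paste(head(rownames(X)[var_pooled == 0], 5), collapse = ", "))
  }

  # drop genes constant within a batch (zero within-batch MS after centering)
  within_ms <- vapply(levels(batch), function(b) {
    xb <- X[, batch == b, drop = FALSE]
    rowMeans((xb - rowMeans(xb))^2)
  }, numeric(nrow(X)))
  degenerate <- rowSums(within_ms == 0) > 0
  if (any(degenerate)) {
    warning("dropping ", sum(degenerate),
            " gene(s) constant within a batch: ",
            paste(head(rownames(X)[degenerate], 5), collapse = ", "),
            call. = FALSE)
    X <- X[!degenerate, , drop = FALSE]
    bm <- bm[!degenerate, , drop = FALSE]
    alpha <- alpha[!degenerate]
    var_pooled <- var_pooled[!degenerate]
  }
  sd_pooled <- sqrt(var_pooled)
  Z <- (X - alpha) / sd_pooled

  gamma_hat <- delta_hat <- gamma_star <- delta_star <-
    matrix(NA_real_, nrow(X), nb, dimnames = list(rownames(X), levels(batch)))
  hyper <- vector("list", nb)
  names(hyper) <- levels(batch)

  for (j in seq_len(nb)) {
    cols <- batch == levels(batch)[j]
    Zb <- Z[, cols, drop = FALSE]
    g_hat <- rowMeans(Zb)
    d_hat <- rowMeans((Zb - g_hat)^2)                     # MLE scale per gene
    g_bar <- mean(g_hat); t2 <- var(g_hat)
    m <- mean(d_hat); s2 <- var(d_hat)
    # inverse-gamma hyperparameters by moments; degenerate spread => the
    # prior is a point mass and shrinkage is complete
    if (is.na(s2) || s2 < 1e-12) {
      a_pr <- Inf; b_pr <- Inf
      d_star <- d_hat
      g_star <- if (is.na(t2) || t2 < 1e-12) rep(g_bar, length(g_hat)) else g_hat
      if (!(is.na(t2) || t2 < 1e-12)) {
        g_star <- (n_b[j] * t2 * g_hat + d_star * g_bar) / (n_b[j] * t2 + d_star)
      }
    } else {
      a_pr <- (2 * s2 + m^2) / s2
      b_pr <- (m * s2 + m^3) / s2
      d_star <- d_hat
      g_star <- g_hat
      ssq <- function(gs) rowSums((Zb - gs)^2)
      if (is.na(t2) || t2 < 1e-12) {
        g_star <- rep(g_bar, length(g_hat))
        d_star <- (b_pr + 0.5 * ssq(g_star)) / (n_b[j] / 2 + a_pr - 1)
      } else {
        for (it in seq_len(100)) {
          g_new <- (n_b[j] * t2 * g_hat + d_star * g_bar) / (n_b[j] * t2 + d_star)
          d_new <- (b_pr + 0.5 * ssq(g_new)) / (n_b[j] / 2 + a_pr - 1)
          conv <- max(abs(g_new - g_star), abs(d_new - d_star))
          g_star <- g_new; d_star <- d_new
          if (conv < 1e-10) break
        }
      }
    }
    gamma_hat[, j] <- g_hat; delta_hat[, j] <- d_hat
    gamma_star[, j] <- g_star; delta_star[, j] <- d_star
    hyper[[j]] <- list(location_prior_mean = g_bar, location_prior_var = t2,
                       scale_prior_a = a_pr, scale_prior_b = b_pr)
    Z[, cols] <- (Zb - g_star) / sqrt(d_star)
  }

  corrected <- Z * sd_pooled + alpha
  out <- expr_matrix(corrected,
                     batch = info$batch[match(colnames(corrected), info$sample_id)],
                     tumor = info$tumor[match(colnames(corrected), info$sample_id)])
  model <- list(grand_mean = alpha, pooled_var = var_pooled,
                gamma_hat = gamma_hat, delta2_hat = delta_hat,
                gamma_star = gamma_star, delta2_star = delta_star,
                hyperparameters = hyper, batch = batch,
                dropped_genes = if (exists("degenerate")) names(degenerate)[degenerate] else character())
  list(corrected = out, model = model)
}
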