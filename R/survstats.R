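# Survival estimation and comparison (Kaplan-Meier product-limit, log-rank),
# correlation with Fisher-z confidence intervals, parametric/nonparametric
# group-comparison dispatch, immunotherapy response tables and ridge-based
# drug-sensitivity prediction.

#' Kaplan-Meier product-limit fit
#'
#' Per group, the product-limit estimator with the simultaneous-event
#' convention at ties; samples censored at an event time count as at risk
#' for that time. With >= 2 groups the log-rank comparison is attached.
#'
#' @param times nonnegative event/censoring times.
#' @param events event indicators in \{0, 1\}.
#' @param groups optional group labels (default: one group).
#' @return `km_fit`: per-group data.frame of `time`, `n_risk`, `n_event`,
#'   `surv`, plus `median` per group and (when applicable) `logrank`.
#' @export
km_fit <- function(times, events, groups = NULL) {
  if (any(times < 0)) stop2("negative times")
  if (!all(events %in% c(0, 1))) stop2("events must be 0/1")
  groups <- factor(groups %||% rep("all", length(times)))
  if (any(table(groups) == 0L)) stop2("empty group")
  fit_one <- function(t, e) {
    tt <- sort(unique(t))
    n_risk <- vapply(tt, function(x) sum(t >= x), numeric(1))
    n_event <- vapply(tt, function(x) sum(t == x & e == 1), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    data.frame(time = tt, n_risk = n_risk, n_event = n_event, surv = surv)
  }
  curves <- lapply(levels(groups), function(g) {
    sel <- groups == g
    fit_one(times[sel], events[sel])
  })
  names(curves) <- levels(groups)
  medians <- vapply(curves, function(cv) {
    below <- cv$time[cv$surv <= 0.5]
    if (length(below)) min(below) else NA_real_
  }, numeric(1))
  out <- list(curves = curves, median = medians, groups = groups)
  if (nlevels(groups) >= 2L) out$logrank <- logrank(times, events, groups)
  class(out) <- "km_fit"
  out
}

#' @export
print.km_fit <- function(x, ...) {
  cat("km_fit with ", length(x$curves), " group(s); median survival: ",
      paste(names(x$median), round(x$median, 2), sep = " = ", collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$logrank)) {
    cat(sprintf("  log-rank chi2 = %.3f, df = %d, p = %.3g\n",
                x$logrank$chi2, x$logrank$df, x$logrank$p))
  }
  invisible(x)
}

#' Log-rank test across groups
#'
#' Observed-minus-expected with the hypergeometric variance at each distinct
#' event time; for more than two groups the quadratic form uses the
#' covariance matrix of the first g - 1 groups. Requires at least one event.
#'
#' @inheritParams km_fit
#' @return List: `chi2`, `df`, `p`, per-group `observed` and `expected`.
#' @export
logrank <- function(times, events, groups) {
  groups <- factor(groups)
  g <- nlevels(groups)
  if (g < 2L) stop2("need >= 2 groups")
  if (sum(events) == 0) stop2("no events observed; log-rank undefined")
  ev_times <- sort(unique(times[events == 1]))
  O <- E <- setNames(numeric(g), levels(groups))
  V <- matrix(0, g, g, dimnames = list(levels(groups), levels(groups)))
  for (t in ev_times) {
    at_risk <- times >= t
    N_t <- sum(at_risk)
    d_t <- sum(times == t & events == 1)
    n_j <- vapply(levels(groups), function(gr) sum(at_risk & groups == gr), numeric(1))
    O <- O + vapply(levels(groups), function(gr)
      sum(times == t & events == 1 & groups == gr), numeric(1))
    E <- E + d_t * n_j / N_t
    if (N_t > 1) {
      frac <- n_j / N_t
      V <- V + d_t * (N_t - d_t) / (N_t - 1) * (diag(frac, g) - outer(frac, frac))
    }
  }
  u <- (O - E)[-g]
  Vsub <- V[-g, -g, drop = FALSE]
  chi2 <- tryCatch(drop(t(u) %*% solve(Vsub, u)),
                   error = function(e) 0)
  df <- g - 1L
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Correlation with t test and Fisher-z confidence interval
#'
#' Pearson (or Spearman, via the same machinery on ranks) correlation with
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, its two-sided p-value, and a 95%
#' Fisher-z interval `tanh(atanh(r) +/- z_0.975 / sqrt(n - 3))`.
#'
#' @param x,y numeric vectors (n >= 3, finite, nonconstant).
#' @param method `"pearson"` or `"spearman"`.
#' @return List: `r`, `n`, `t`, `df`, `p`, `ci` (length-2).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop2("need >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop2("zero variance input")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  r <- cor(x, y)
  tt <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), n - 2)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  half <- qnorm(0.975) / sqrt(n - 3)
  ci <- tanh(c(z - half, z + half))
  list(r = r, n = n, t = tt, df = n - 2L, p = p, ci = ci, method = method)
}

#' Compare a quantity across groups with the standard test dispatch
#'
#' Two groups: Student's t when both pass Shapiro-Wilk normality at
#' alpha = 0.05, otherwise Wilcoxon rank-sum. More than two: one-way ANOVA
#' when every group passes, otherwise Kruskal-Wallis. All two-sided.
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 non-empty groups).
#' @param force `"auto"` (default) applies the normality gate;
#'   `"parametric"`/`"nonparametric"` force the branch.
#' @return List: `statistic`, `p`, `method`.
#' @export
group_compare <- function(values, groups, force = c("auto", "parametric", "nonparametric")) {
  force <- match.arg(force)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop2("need >= 2 groups")
  if (any(table(groups) == 0L)) stop2("empty group")
  split_v <- split(values, groups)
  normalish <- function(v) {
    if (length(v) < 3L || length(unique(v)) < 3L) return(FALSE)
    shapiro.test(v)$p.value >= 0.05
  }
  parametric <- switch(force,
                       auto = all(vapply(split_v, normalish, logical(1))),
                       parametric = TRUE,
                       nonparametric = FALSE)
  if (nlevels(groups) == 2L) {
    if (parametric) {
      tt <- t.test(split_v[[2]], split_v[[1]], var.equal = TRUE)
      list(statistic = unname(tt$statistic), p = tt$p.value, method = "t")
    } else {
      if (sd(values) == 0) return(list(statistic = NA_real_, p = 1, method = "wilcoxon"))
      wt <- suppressWarnings(wilcox.test(split_v[[2]], split_v[[1]]))
      list(statistic = unname(wt$statistic), p = wt$p.value, method = "wilcoxon")
    }
  } else {
    if (parametric) {
      fit <- summary(aov(values ~ groups))[[1]]
      list(statistic = fit[["F value"]][1], p = fit[["Pr(>F)"]][1], method = "anova")
    } else {
      if (sd(values) == 0) return(list(statistic = 0, p = 1, method = "kruskal"))
      kt <- kruskal.test(values, groups)
      list(statistic = unname(kt$statistic), p = kt$p.value, method = "kruskal")
    }
  }
}

#' Immunotherapy response analysis by score group
#'
#' Builds the 2x2 responder table (CR/PR vs SD/PD by high/low score group),
#' tests it with Fisher's exact test (or Pearson chi-square without
#' continuity correction when every expected count is >= 5), and, when raw
#' scores are supplied, compares scores between responders and
#' non-responders by Wilcoxon.
#'
#' @param score_groups `"high"`/`"low"` labels per sample.
#' @param response_labels RECIST labels in CR/PR/SD/PD (NA dropped).
#' @param scores optional raw per-sample scores.
#' @return List: `table` (2x2 counts), `rates` (CR/PR rate per group),
#'   `p`, `test`, and optionally `score_by_response` (`statistic`, `p`).
#' @export
response_analysis <- function(score_groups, response_labels, scores = NULL) {
  keep <- !is.na(response_labels)
  score_groups <- score_groups[keep]
  response_labels <- response_labels[keep]
  if (!is.null(scores)) scores <- scores[keep]
  bad <- !response_labels %in% c("CR", "PR", "SD", "PD")
  if (any(bad)) stop2("unknown response label(s): ",
                      paste(unique(response_labels[bad]), collapse = ", "))
  if (!all(score_groups %in% c("high", "low"))) stop2("score groups must be high/low")
  responder <- factor(ifelse(response_labels %in% c("CR", "PR"), "CR/PR", "SD/PD"),
                      levels = c("CR/PR", "SD/PD"))
  grp <- factor(score_groups, levels = c("high", "low"))
  tab <- table(grp, responder)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected > 5)) {
    ht <- chisq.test(tab, correct = FALSE)
    test <- "chi-square"
  } else {
    ht <- fisher.test(tab)
    test <- "fisher"
  }
  rates <- tab[, "CR/PR"] / rowSums(tab)
  out <- list(table = tab, rates = rates, p = ht$p.value, test = test)
  if (!is.null(scores)) {
    wt <- suppressWarnings(wilcox.test(scores[responder == "CR/PR"],
                                       scores[responder == "SD/PD"]))
    out$score_by_response <- list(statistic = unname(wt$statistic), p = wt$p.value)
  }
  out
}

# Closed-form ridge solution on centered y / standardized X.
ridge_fit <- function(X, y, lambda) {
  p <- ncol(X)
  A <- crossprod(X) + diag(lambda, p)
  drop(solve(A, crossprod(X, y)))
}

#' Ridge-based drug-sensitivity (log-IC50) prediction
#'
#' Trains, per drug, a ridge regression of log-IC50 on cell-line expression
#' restricted to the genes shared with the cohort, standardized by the
#' panel's gene means/SDs (panel-anchored z-scoring); the penalty is chosen
#' by k-fold cross-validated mean squared error over `lambda_grid`, and the
#' fitted model predicts each cohort sample's log-IC50.
#'
#' @param panel_expr genes x lines training expression matrix.
#' @param panel_ic50 lines x drugs matrix of log-IC50.
#' @param cohort_expr [expr_matrix()] or genes x samples matrix to predict.
#' @param lambda_grid positive ridge penalties (default `10^seq(-2, 3)`).
#' @param cv_folds cross-validation folds (default 10; must not exceed the
#'   number of lines).
#' @param seed RNG seed for the fold assignment.
#' @return List: `predicted` (samples x drugs), `lambda` (chosen per drug),
#'   `shared_genes`.
#' @export
ridge_ic50 <- function(panel_expr, panel_ic50, cohort_expr,
                       lambda_grid = 10^seq(-2, 3, by = 1), cv_folds = 10,
                       seed = NULL) {
  if (length(lambda_grid) == 0L) stop2("lambda_grid is empty")
  if (any(lambda_grid <= 0)) stop2("ridge penalties must be > 0")
  Xp <- as_values(panel_expr)
  Xc <- as_values(cohort_expr)
  panel_ic50 <- as.matrix(panel_ic50)
  shared <- intersect(rownames(Xp), rownames(Xc))
  if (length(shared) < 10L) stop2("panel and cohort share fewer than 10 genes")
  n_lines <- ncol(Xp)
  if (n_lines < cv_folds) stop2("degenerate panel: fewer lines than cv_folds")
  if (nrow(panel_ic50) != n_lines) stop2("ic50 rows must match panel lines")
  if (!is.null(seed)) set.seed(seed)

  mu <- rowMeans(Xp[shared, , drop = FALSE])
  sg <- apply(Xp[shared, , drop = FALSE], 1L, sd)
  ok <- sg > 0
  shared <- shared[ok]; mu <- mu[ok]; sg <- sg[ok]
  Ztrain <- t((Xp[shared, , drop = FALSE] - mu) / sg)   # lines x genes
  Ztest <- t((Xc[shared, , drop = FALSE] - mu) / sg)    # samples x genes

  folds <- sample(rep_len(seq_len(cv_folds), n_lines))
  n_drugs <- ncol(panel_ic50)
  predicted <- matrix(NA_real_, nrow(Ztest), n_drugs,
                      dimnames = list(rownames(Ztest), colnames(panel_ic50)))
  lambda_sel <- setNames(numeric(n_drugs), colnames(panel_ic50))
  for (dcol in seq_len(n_drugs)) {
    y <- panel_ic50[, dcol]
    cv_mse <- vapply(lambda_grid, function(lam) {
      errs <- vapply(seq_len(cv_folds), function(f) {
        tr <- folds != f
        y_tr <- y[tr]
        beta <- ridge_fit(Ztrain[tr, , drop = FALSE], y_tr - mean(y_tr), lam)
        pred <- mean(y_tr) + drop(Ztrain[!tr, , drop = FALSE] %*% beta)
        mean((y[!tr] - pred)^2)
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    lam <- lambda_grid[which.min(cv_mse)]
    beta <- ridge_fit(Ztrain, y - mean(y), lam)
    predicted[, dcol] <- mean(y) + drop(Ztest %*% beta)
    lambda_sel[dcol] <- lam
  }
  list(predicted = predicted, lambda = lambda_sel, shared_genes = shared)
}
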