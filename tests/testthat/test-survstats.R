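# Survival machinery (KM, log-rank) against closed forms, hand tables and
# the survival package; correlation with Fisher-z CI (permutation oracle and
# coverage); group-comparison dispatch; response tables; ridge IC50.

test_that("KM with no censoring equals the empirical survival function", {
  km <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$curves$all$surv, c(2 / 3, 1 / 3, 0))
  km2 <- km_fit(c(4, 2, 7, 1), rep(1, 4))
  expect_equal(km2$curves$all$surv, c(3, 2, 1, 0) / 4)
})

test_that("all-censored data keeps survival at 1", {
  km <- km_fit(c(1, 2, 3, 4), rep(0, 4))
  expect_true(all(km$curves$all$surv == 1))
  expect_true(is.na(km$median[["all"]]))
})

test_that("six-subject mixed-censoring fixture matches the hand-computed table", {
  # times 1,2+,3,4,5+,6 (+ censored): steps at 1, 3, 4, 6
  t <- c(1, 2, 3, 4, 5, 6); e <- c(1, 0, 1, 1, 0, 1)
  km <- km_fit(t, e)
  cv <- km$curves$all
  hand <- c(5 / 6, 5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3,
            5 / 6 * 3 / 4 * 2 / 3, 0)
  expect_equal(cv$surv, hand, tolerance = 1e-12)
  expect_equal(cv$n_risk, c(6, 5, 4, 3, 2, 1))
  skip_if_not_installed("survival")
  sf <- survival::survfit(survival::Surv(t, e) ~ 1)
  expect_equal(cv$surv[cv$n_event > 0], sf$surv[sf$n.event > 0], tolerance = 1e-12)
})

test_that("log-rank is zero on duplicated groups and matches a direct O-E/V oracle", {
  t <- c(1, 3, 5, 7, 2, 4); e <- c(1, 1, 0, 1, 1, 0)
  lr <- logrank(c(t, t), c(e, e), rep(c("a", "b"), each = 6))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  # two groups, non-overlapping event times, all events
  t2 <- c(1, 2, 3, 10, 11, 12); e2 <- rep(1, 6)
  g2 <- rep(c("early", "late"), each = 3)
  lr2 <- logrank(t2, e2, g2)
  O <- E <- V <- 0
  for (tt in t2) {                        # independent O-E/V evaluation
    at <- t2 >= tt
    N <- sum(at); d <- 1
    n1 <- sum(at & g2 == "early")
    O <- O + (g2[t2 == tt] == "early")
    E <- E + n1 / N
    if (N > 1) V <- V + (n1 / N) * (1 - n1 / N) * (N - d) / (N - 1)
  }
  expect_equal(lr2$chi2, (O - E)^2 / V, tolerance = 1e-12)
  skip_if_not_installed("survival")
  sd2 <- survival::survdiff(survival::Surv(t2, e2) ~ g2)
  expect_equal(lr2$chi2, sd2$chisq, tolerance = 1e-10)
})

test_that("log-rank is invariant under increasing time transforms and needs events", {
  set.seed(61)
  t <- rexp(40); e <- rbinom(40, 1, 0.7); g <- rep(c("a", "b"), 20)
  lr1 <- logrank(t, e, g)
  lr2 <- logrank(log1p(t), e, g)
  expect_equal(lr1$chi2, lr2$chi2, tolerance = 1e-12)
  expect_error(logrank(t, rep(0, 40), g), "no events")
})

test_that("three-group log-rank agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(62)
  t <- rexp(60, rep(c(0.1, 0.2, 0.4), each = 20))
  e <- rbinom(60, 1, 0.8)
  g <- rep(c("a", "b", "c"), each = 20)
  lr <- logrank(t, e, g)
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_equal(lr$chi2, sd$chisq, tolerance = 1e-8)
  expect_equal(lr$df, 2L)
})

test_that("high/low score split is powered at the planted hazard", {
  # 50 seeded replicates: signature-based score, survival cutpoint, log-rank
  reps <- 50
  hits <- 0
  for (r in seq_len(reps)) {
    co <- generate_cohort(sim_config(n_genes = 250, immune_block_size = 5,
                                     stromal_block_size = 5, n_normal = 0,
                                     seed = 100 + r))
    tum <- tumor_ids(co)
    part <- structure(list(signature_A = co$truth$signature_A,
                           signature_B = co$truth$signature_B,
                           retained_A = NULL, retained_B = NULL),
                      class = "signature_partition")
    sc <- compute_score(co$expression$values[, tum], part)
    clin <- co$clinical[match(tum, co$clinical$sample_id), ]
    sc <- dichotomize(sc, clin)
    lr <- logrank(clin$os_time, clin$os_event, sc$group)
    if (lr$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("correlation machinery: identity, formula consistency, permutation oracle", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 10)
  r1 <- correlate(x, x)
  expect_equal(r1$r, 1)
  expect_equal(r1$ci[2], 1)

  # printed-format consistency: r = -0.63 at n = 930 implies t near -24.9
  r <- -0.63; n <- 930
  t_lo <- -0.635 * sqrt(n - 2) / sqrt(1 - 0.635^2)
  t_hi <- -0.625 * sqrt(n - 2) / sqrt(1 - 0.625^2)
  expect_lt(t_lo, -24.87); expect_gt(t_hi, -24.87)
  t_mid <- r * sqrt(n - 2) / sqrt(1 - r^2)
  expect_equal(t_mid, -24.65, tolerance = 0.01)

  set.seed(63)
  a <- rnorm(10); b <- 0.5 * a + rnorm(10)
  res <- correlate(a, b)
  perm <- replicate(1e4, abs(cor(a, sample(b))))
  p_perm <- mean(perm >= abs(res$r))
  expect_lt(abs(res$p - p_perm), 0.02)
  skip_if_not_installed("survival")   # base cor.test used as oracle anyway
  ct <- cor.test(a, b)
  expect_equal(res$p, ct$p.value, tolerance = 1e-10)
  expect_equal(res$ci, unname(as.vector(ct$conf.int)), tolerance = 1e-10)
})

test_that("Fisher-z interval has near-nominal coverage", {
  set.seed(64)
  rho <- 0.4; n <- 50; reps <- 1000
  covered <- 0
  for (i in seq_len(reps)) {
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    ci <- correlate(x, y)$ci
    if (ci[1] <= rho && rho <= ci[2]) covered <- covered + 1
  }
  expect_gte(covered / reps, 0.92)
  expect_lte(covered / reps, 0.98)
})

test_that("correlate input validation and spearman ranks", {
  expect_error(correlate(1:2, 1:2), "3")
  expect_error(correlate(rep(1, 5), 1:5), "variance")
  set.seed(65)
  x <- rnorm(20); y <- x^3 + rnorm(20, sd = 0.01)
  expect_gt(correlate(x, y, method = "spearman")$r, 0.99)
})

test_that("group comparison: closed-form Kruskal-Wallis and dispatch", {
  res0 <- group_compare(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3),
                        force = "nonparametric")
  expect_equal(res0$p, 1, tolerance = 1e-10)

  # H = 7.2 for {1,2,3},{4,5,6},{7,8,9}: hand rank formula, no ties
  res <- group_compare(1:9, rep(c("a", "b", "c"), each = 3),
                       force = "nonparametric")
  expect_equal(res$statistic, 7.2, tolerance = 1e-12)
  expect_equal(res$method, "kruskal")

  # two groups route to the two-sample tests
  set.seed(66)
  v <- rnorm(20)
  res2 <- group_compare(v, rep(c("a", "b"), 10))
  expect_true(res2$method %in% c("t", "wilcoxon"))
  expect_error(group_compare(v, rep("a", 20)), "2 groups")
})

test_that("identical groups give H = 0, p = 1", {
  v <- rep(c(5, 7, 9), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  v_identical <- c(5, 7, 9, 5, 7, 9, 5, 7, 9)
  res <- group_compare(v_identical, g, force = "nonparametric")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
})

test_that("response analysis: exact Fisher p on the extreme table", {
  groups <- rep(c("high", "low"), each = 10)
  resp <- c(rep("CR", 10), rep("PD", 10))
  res <- response_analysis(groups, resp)
  expect_equal(res$test, "fisher")
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-10)
  expect_equal(unname(res$rates), c(1, 0))
})

test_that("response analysis: identical rates give p = 1; labels validated", {
  groups <- rep(c("high", "low"), each = 20)
  resp <- rep(c("PR", "SD"), 20)
  res <- response_analysis(groups, resp)
  expect_equal(res$p, 1, tolerance = 1e-10)
  expect_error(response_analysis(groups, rep("XX", 40)), "unknown response")
})

test_that("planted logistic response structure yields a higher CR/PR rate when scores are high", {
  co <- default_cohort()
  tum <- tumor_ids(co)
  z <- co$truth$z[tum]
  groups <- ifelse(z > median(z), "high", "low")
  resp <- co$clinical$response[match(tum, co$clinical$sample_id)]
  res <- response_analysis(groups, resp, scores = z)
  expect_gt(res$rates[["high"]], res$rates[["low"]])
  expect_lt(res$p, 0.01)
  expect_lt(res$score_by_response$p, 0.01)
})

test_that("ridge prediction: noiseless limit, full shrinkage, held-out recovery", {
  panel <- generate_reference_panel(n_lines = 100, n_genes = 50, n_drugs = 3,
                                    noise_sd = 0, seed = 71)
  tr <- 1:70; te <- 71:100
  fit0 <- ridge_ic50(panel$expression[, tr], panel$ic50[tr, ],
                     panel$expression[, te], lambda_grid = 1e-6, cv_folds = 5,
                     seed = 1)
  for (d in colnames(panel$ic50)) {
    expect_gte(cor(fit0$predicted[, d], panel$ic50[te, d]), 0.999)
  }

  # lambda -> Inf: constant at the panel mean
  fit_inf <- ridge_ic50(panel$expression[, tr], panel$ic50[tr, ],
                        panel$expression[, te], lambda_grid = 1e12,
                        cv_folds = 5, seed = 1)
  expect_lt(max(abs(fit_inf$predicted[, 1] - mean(panel$ic50[tr, 1]))), 1e-3)

  # default noisy panel: held-out r >= 0.8 with CV-chosen lambda
  panel2 <- generate_reference_panel(seed = 72)
  tr2 <- 1:210; te2 <- 211:300
  fit <- ridge_ic50(panel2$expression[, tr2], panel2$ic50[tr2, ],
                    panel2$expression[, te2], seed = 2)
  for (d in colnames(panel2$ic50)) {
    expect_gte(cor(fit$predicted[, d], panel2$ic50[te2, d]), 0.8)
  }

  # equivariant under gene reordering
  perm <- sample(rownames(panel2$expression))
  fit_p <- ridge_ic50(panel2$expression[perm, tr2], panel2$ic50[tr2, ],
                      panel2$expression[, te2], seed = 2)
  expect_equal(fit_p$predicted, fit$predicted, tolerance = 1e-8)
})

test_that("ridge agrees with glmnet at a fixed penalty", {
  skip_if_not_installed("glmnet")
  panel <- generate_reference_panel(n_lines = 60, n_genes = 40, n_drugs = 1,
                                    seed = 73)
  X <- t(scale(t(panel$expression)))     # gene-standardized
  y <- panel$ic50[, 1]
  n <- length(y)
  lam <- 5
  mine <- m5Cscope:::ridge_fit(t(X), y - mean(y), lam)
  # glmnet solves 1/(2n) RSS + lambda/2 |beta|^2 on internally y-standardized
  # data, so its lambda maps to lam/n times the MLE sd of y
  sdy <- sd(y) * sqrt((n - 1) / n)
  gl <- glmnet::glmnet(t(X), y, alpha = 0, lambda = lam / n * sdy,
                       standardize = FALSE, intercept = TRUE,
                       thresh = 1e-16)
  expect_equal(mine, as.vector(coef(gl))[-1], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("ridge input validation", {
  panel <- generate_reference_panel(n_lines = 20, n_genes = 30, n_drugs = 2,
                                    seed = 74)
  expect_error(ridge_ic50(panel$expression, panel$ic50, panel$expression,
                          lambda_grid = c(-1, 2)), "> 0")
  expect_error(ridge_ic50(panel$expression, panel$ic50, panel$expression,
                          lambda_grid = numeric()), "empty")
  expect_error(ridge_ic50(panel$expression, panel$ic50, panel$expression,
                          cv_folds = 30), "degenerate")
  other <- panel$expression[1:5, ]
  rownames(other) <- paste0("zz", 1:5)
  expect_error(ridge_ic50(panel$expression, panel$ic50, other), "10 genes")
})
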