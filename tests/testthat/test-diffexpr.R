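# Differential expression: exact Wilcoxon enumeration oracle, planted
# tumor-shift recovery, the moderated F against a directly coded formula
# oracle and its no-shrinkage limits, limma cross-check of the variance
# shrinkage, multiplicity adjustment, and DEG intersection.

test_that("Wilcoxon W and p match exhaustive enumeration on {1,2,3} vs {4,5,6}", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), 1, dimnames = list("g1", paste0("s", 1:6)))
  groups <- rep(c("a", "b"), each = 3)
  res <- two_group_test(x, groups, method = "wilcoxon")

  # oracle: enumerate all 20 assignments of 3 ranks to group b
  vals <- 1:6
  combos <- combn(6, 3)
  W_all <- apply(combos, 2, function(ix) sum(rank(vals)[ix]) - 3 * 4 / 2)
  W_obs <- sum(rank(vals)[4:6]) - 6           # group b holds ranks 4..6
  p_exact <- min(1, 2 * min(mean(W_all <= W_obs), mean(W_all >= W_obs)))
  expect_equal(res$statistic, W_obs)
  expect_equal(res$p, p_exact, tolerance = 1e-12)
})

test_that("identical values in both groups give p = 1 and logFC 0", {
  x <- matrix(5, 1, 6, dimnames = list("g1", paste0("s", 1:6)))
  res <- two_group_test(x, rep(c("a", "b"), each = 3), method = "wilcoxon")
  expect_equal(res$p, 1)
  expect_equal(res$logfc, 0)
  expect_equal(res$statistic, 3 * 3 / 2)      # mid-rank convention
})

test_that("planted tumor-shift regulators are flagged; null regulators are not", {
  co <- default_cohort()
  reg <- m5c_regulators()
  res <- two_group_test(co$expression$values[reg, ],
                        ifelse(co$expression$samples$tumor, "tumor", "normal"))
  dirs <- co$truth$regulator_tumor_direction[res$gene]
  expect_true(all(res$p_adj[dirs != 0] < 0.05))
  expect_true(all(res$p_adj[dirs == 0] > 0.05))
  # logFC sign matches the planted direction
  expect_true(all(sign(res$logfc[dirs != 0]) == dirs[dirs != 0]))
})

test_that("moderated F with d0 = 0 equals the classical ANOVA F", {
  set.seed(31)
  X <- matrix(rnorm(20 * 9), 20, dimnames = list(paste0("g", 1:20), paste0("s", 1:9)))
  groups <- rep(c("a", "b", "c"), each = 3)
  res <- moderated_anova(X, groups, prior_df = 0)
  f_classic <- vapply(seq_len(20), function(g)
    summary(aov(X[g, ] ~ factor(groups)))[[1]][["F value"]][1], numeric(1))
  expect_lt(max(abs(res$F - f_classic) / f_classic), 1e-10)
})

test_that("all genes sharing one variance make shrinkage a no-op", {
  # identical residual variance for every gene: s0^2 = s^2, moderated = classical
  set.seed(32)
  base <- rnorm(9)
  X <- matrix(rep(base, each = 12), 12, byrow = FALSE,
              dimnames = list(paste0("g", 1:12), paste0("s", 1:9)))
  shift <- rnorm(12, sd = 2)
  X <- X + shift                      # per-gene location offsets only
  groups <- rep(c("a", "b", "c"), each = 3)
  expect_warning(res <- moderated_anova(X, groups), "complete shrinkage")
  expect_equal(max(abs(res$s2 - res$s2[1])), 0, tolerance = 1e-12)
  f_classic <- vapply(seq_len(12), function(g)
    summary(aov(X[g, ] ~ factor(groups)))[[1]][["F value"]][1], numeric(1))
  expect_equal(res$F, f_classic, tolerance = 1e-8)
})

test_that("moderated F matches an independently coded formula oracle", {
  set.seed(33)
  X <- matrix(rnorm(20 * 9, sd = rep(runif(20, 0.5, 2), 9)), 20,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:9)))
  groups <- rep(c("a", "b", "c"), each = 3)
  res <- moderated_anova(X, groups)
  oracle <- moderated_f_oracle(X, groups, attr(res, "d0"), attr(res, "s02"))
  expect_lt(max(abs(res$F - oracle)), 1e-8)
})

test_that("variance shrinkage agrees with limma's empirical Bayes", {
  skip_if_not_installed("limma")
  set.seed(34)
  X <- matrix(rnorm(200 * 12, sd = rep(runif(200, 0.5, 2), 12)), 200,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:12)))
  groups <- rep(c("a", "b", "c"), each = 4)
  res <- moderated_anova(X, groups)
  sq <- limma::squeezeVar(res$s2, df = ncol(X) - 3)
  expect_equal(attr(res, "d0"), sq$df.prior, tolerance = 0.05)
  s2_post <- (attr(res, "d0") * attr(res, "s02") + 9 * res$s2) /
    (attr(res, "d0") + 9)
  expect_equal(s2_post, sq$var.post, tolerance = 0.01)
})

test_that("adjustment matches hand-computed values and stays monotone", {
  p <- c(0.01, 0.02, 0.03)
  expect_equal(adjust_p(p, "bonferroni"), c(0.03, 0.06, 0.09))
  expect_equal(adjust_p(p, "bh"), c(0.03, 0.03, 0.03))
  expect_equal(adjust_p(0.2, "bh"), 0.2)
  expect_equal(adjust_p(0.2, "bonferroni"), 0.2)
  expect_error(adjust_p(c(0.5, 1.2)), "0, 1")
  # monotone in raw p after sorting, and never below raw
  set.seed(35)
  praw <- runif(100)
  padj <- adjust_p(praw, "bh")
  expect_true(all(padj >= praw - 1e-15))
  ord <- order(praw)
  expect_true(all(diff(padj[ord]) >= -1e-15))
})

test_that("false-positive gene fraction stays controlled on a null cohort", {
  co <- generate_cohort(sim_config(n_samples_per_cluster = 30, n_genes = 2000,
                                   cluster_shift = 0, signature_coef = 0,
                                   immune_shift = 0, tumor_shift = 0,
                                   batch_shift = 0, batch_scale = 1,
                                   stromal_coef = 0, seed = 36))
  tum <- tumor_ids(co)
  res <- suppressWarnings(
    moderated_anova(co$expression$values[, tum], co$truth$cluster[tum]))
  expect_lte(mean(res$p_adj < 0.05), 0.07)
})

test_that("DEG intersection preserves order, counts, and handles edge cases", {
  out <- intersect_degs(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(as.vector(out), c("b", "c"))
  expect_equal(attr(out, "counts")[["intersection"]], 2L)
  expect_equal(as.vector(intersect_degs(letters[1:3], letters[1:3])), letters[1:3])
  expect_warning(empty <- intersect_degs("a", "b"), "empty")
  expect_length(empty, 0)
  expect_error(intersect_degs(character(), "a"), "nonempty")
})

test_that("cluster DEGs intersected with the planted tumor list recover both signals", {
  co <- default_cohort()
  tum <- tumor_ids(co)
  res <- moderated_anova(co$expression$values[, tum], co$truth$cluster[tum])
  cluster_degs <- res$gene[res$p_adj < 0.05]
  both <- intersect_degs(cluster_degs, co$truth$tumor_deg_genes)
  planted_both <- c(co$truth$signature_A, co$truth$signature_B)
  expect_gte(mean(planted_both %in% both), 0.9)
})
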