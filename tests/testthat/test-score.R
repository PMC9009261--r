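# Signature partition, shadow-feature selection, the score construction and
# the maximally selected survival cutpoint (with a brute-force scan oracle).

test_that("monotone genes land in signature A; constant genes warn into B", {
  labels <- setNames(rep(c("A", "B", "C"), each = 4), paste0("s", 1:12))
  clin <- data.frame(sample_id = names(labels),
                     os_time = rep(c(5, 10, 20), each = 4),  # C best survival
                     os_event = 1, tumor = TRUE, batch = "B1")
  x <- rbind(up = rep(c(1, 2, 3), each = 4),       # increases with encoding
             down = rep(c(3, 2, 1), each = 4),
             flat = rep(1, 12))
  colnames(x) <- names(labels)
  expect_warning(part <- partition_signatures(x, labels, clin), "constant")
  expect_true("up" %in% part$signature_A)
  expect_true(all(c("down", "flat") %in% part$signature_B))
  expect_equal(part$rho[["up"]], 1)
  # encoding orders clusters by survival: C (20) highest code
  expect_equal(names(which.max(part$encoding)), "C")
})

test_that("planted signature blocks are partitioned correctly", {
  co <- default_cohort()
  tum <- tumor_ids(co)
  gene_cl <- cluster_stratify(co$expression$values[, tum],
                              c(co$truth$signature_A, co$truth$signature_B),
                              label_style = "letter", B = 100, seed = 2)
  clin <- co$clinical[match(tum, co$clinical$sample_id), ]
  degs <- c(co$truth$signature_A, co$truth$signature_B)
  part <- partition_signatures(co$expression$values[degs, tum], gene_cl, clin)
  expect_gte(mean(co$truth$signature_A %in% part$signature_A), 0.95)
  expect_gte(mean(co$truth$signature_B %in% part$signature_B), 0.95)
})

test_that("shadow selection: global null confirms nothing", {
  set.seed(51)
  X <- matrix(rnorm(60 * 5), 60, dimnames = list(NULL, paste0("v", 1:5)))
  y <- sample(c("a", "b"), 60, TRUE)
  res <- shadow_select(X, y, max_iter = 20, seed = 1)
  expect_equal(sum(res$decision == "confirmed"), 0L)
})

test_that("shadow selection: the single informative feature is confirmed", {
  set.seed(52)
  n <- 200
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(signal = as.numeric(y == "b") + rnorm(n, sd = 0.05),
             matrix(rnorm(n * 20), n, dimnames = list(NULL, NULL)))
  colnames(X)[-1] <- paste0("noise", 1:20)
  res <- shadow_select(X, y, max_iter = 100, seed = 2)
  expect_true("signal" %in% res$selected)
  expect_equal(unname(res$decision["signal"]), "confirmed")
  expect_gte(sum(res$decision[paste0("noise", 1:20)] == "rejected"), 18)
})

test_that("a single iteration leaves every feature tentative", {
  set.seed(53)
  X <- matrix(rnorm(40 * 4), 40, dimnames = list(NULL, paste0("v", 1:4)))
  y <- rep(c("a", "b"), each = 20)
  res <- shadow_select(X, y, max_iter = 1, seed = 3)
  expect_true(all(res$decision == "tentative"))
  expect_equal(res$iterations, 1L)
  # tentative features are kept by default, dropped on request
  expect_setequal(res$selected, paste0("v", 1:4))
  res2 <- shadow_select(X, y, max_iter = 1, seed = 3, keep_tentative = FALSE)
  expect_length(res2$selected, 0)
})

test_that("score reduces to PC1A with empty B and negates under A/B swap", {
  x <- random_expr(12, 30, seed = 54)
  part <- structure(list(signature_A = rownames(x)[1:6],
                         signature_B = rownames(x)[7:12],
                         retained_A = NULL, retained_B = NULL),
                    class = "signature_partition")
  sc <- compute_score(x, part)
  expect_equal(sc$m5c_score, sc$pc1a - sc$pc1b, tolerance = 1e-12)

  swapped <- part
  swapped$signature_A <- part$signature_B
  swapped$signature_B <- part$signature_A
  sc2 <- compute_score(x, swapped)
  expect_equal(sc2$m5c_score, -sc$m5c_score, tolerance = 1e-10)

  only_a <- part; only_a$signature_B <- character()
  sc3 <- compute_score(x, only_a)
  expect_equal(sc3$m5c_score, sc3$pc1a, tolerance = 1e-12)
  expect_true(all(sc3$pc1b == 0))

  no_a <- part; no_a$signature_A <- character()
  expect_error(compute_score(x, no_a), "signature A")
})

test_that("score orientation follows signature expression and recovers planted z", {
  co <- default_cohort()
  tum <- tumor_ids(co)
  part <- structure(list(signature_A = co$truth$signature_A,
                         signature_B = co$truth$signature_B,
                         retained_A = NULL, retained_B = NULL),
                    class = "signature_partition")
  sc <- compute_score(co$expression$values[, tum], part)
  # PC1A rises with mean signature-A expression (orientation rule)
  za <- rowMeans(scale(t(co$expression$values[co$truth$signature_A, tum])))
  expect_gt(cor(sc$pc1a, za), 0)
  z <- co$truth$z[tum]
  hi <- z >= quantile(z, 0.75); lo <- z <= quantile(z, 0.25)
  p <- wilcox.test(sc$m5c_score[hi], sc$m5c_score[lo],
                   alternative = "greater")$p.value
  expect_lt(p, 0.01)
  # gene/sample order invariance of the score
  perm_genes <- sample(rownames(co$expression$values[c(part$signature_A, part$signature_B), ]))
  sc_perm <- compute_score(co$expression$values[perm_genes, tum], part)
  expect_equal(sc_perm$m5c_score, sc$m5c_score, tolerance = 1e-10)
})

test_that("cutpoint equals the maximum of an exhaustive scan on random fixtures", {
  set.seed(55)
  brute_force <- function(s, times, events, minprop) {
    n <- length(s)
    cands <- sort(unique(s))
    cands <- cands[vapply(cands, function(c)
      sum(s <= c) >= ceiling(minprop * n) && sum(s > c) >= ceiling(minprop * n),
      logical(1))]
    zs <- vapply(cands, function(c) m5Cscope:::logrank_z(times, events, s > c),
                 numeric(1))
    list(cut = cands[which.max(abs(zs))], z = max(abs(zs)))
  }
  for (i in 1:50) {
    n <- 40
    sc <- structure(data.frame(sample_id = paste0("s", 1:n),
                               pc1a = 0, pc1b = 0, m5c_score = rnorm(n)),
                    class = c("score_result", "data.frame"))
    clin <- data.frame(sample_id = paste0("s", 1:n),
                       os_time = rexp(n, 0.1), os_event = rbinom(n, 1, 0.7),
                       tumor = TRUE, batch = "B1")
    out <- dichotomize(sc, clin, minprop = 0.1)
    bf <- brute_force(sc$m5c_score, clin$os_time, clin$os_event, 0.1)
    expect_equal(attr(out, "cutpoint"), bf$cut)
    expect_equal(abs(attr(out, "cutpoint_statistic")), bf$z, tolerance = 1e-12)
  }
})

test_that("minprop = 0.5 with even n leaves exactly the median split", {
  set.seed(56)
  n <- 20
  sc <- structure(data.frame(sample_id = paste0("s", 1:n), pc1a = 0, pc1b = 0,
                             m5c_score = rnorm(n)),
                  class = c("score_result", "data.frame"))
  clin <- data.frame(sample_id = paste0("s", 1:n), os_time = rexp(n, 0.1),
                     os_event = 1, tumor = TRUE, batch = "B1")
  out <- dichotomize(sc, clin, minprop = 0.5)
  expect_equal(attr(out, "cutpoint"), sort(sc$m5c_score)[n / 2])
  expect_equal(sum(out$group == "low"), n / 2)
})

test_that("a planted hazard step near score zero is recovered", {
  set.seed(57)
  n <- 300
  s <- rnorm(n)
  # hazard doubles above the step at 0
  times <- rexp(n, rate = ifelse(s > 0, 0.02, 0.2))
  cens <- runif(n, 0, 40)
  clin <- data.frame(sample_id = paste0("s", 1:n),
                     os_time = pmin(times, cens),
                     os_event = as.integer(times <= cens),
                     tumor = TRUE, batch = "B1")
  sc <- structure(data.frame(sample_id = paste0("s", 1:n), pc1a = 0, pc1b = 0,
                             m5c_score = s),
                  class = c("score_result", "data.frame"))
  out <- dichotomize(sc, clin)
  band <- quantile(s, c(0.4, 0.6))
  expect_gte(attr(out, "cutpoint"), band[[1]])
  expect_lte(attr(out, "cutpoint"), band[[2]])
  # high group must be the long-lived one
  km <- km_fit(clin$os_time, clin$os_event, out$group)
  expect_gt(km$median[["high"]], km$median[["low"]])
})
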