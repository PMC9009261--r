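# Shared fixtures. Cohorts are generated in code (never stored); the
# default-condition cohort is cached per test run since several files probe
# different planted structures of the same object.

.fixture_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixture_cache$default)) {
    .fixture_cache$default <- generate_cohort(sim_config())
  }
  .fixture_cache$default
}

# A small, fast cohort for structural (non-power) checks.
small_config <- function(...) {
  sim_config(n_samples_per_cluster = 20, n_genes = 400, n_normal = 5,
             immune_block_size = 20, stromal_block_size = 20, ...)
}

small_cohort <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- generate_cohort(small_config())
  }
  .fixture_cache$small
}

tumor_ids <- function(cohort) cohort$clinical$sample_id[cohort$clinical$tumor]

# Independent moderated-F evaluation (per-gene lm + explicit posterior
# variance), used as the formula oracle against moderated_anova().
moderated_f_oracle <- function(X, groups, d0, s02) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- ncol(X)
  vapply(seq_len(nrow(X)), function(g) {
    x <- X[g, ]
    fit <- lm(x ~ groups)
    msb <- anova(fit)[["Mean Sq"]][1]
    s2 <- sum(residuals(fit)^2) / (n - k)
    s2_post <- if (is.infinite(d0)) s02 else (d0 * s02 + (n - k) * s2) / (d0 + n - k)
    msb / s2_post
  }, numeric(1))
}

# Random labelled expression matrix for generic API checks.
random_expr <- function(n_genes = 20, n_samples = 10, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}
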