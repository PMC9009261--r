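# Synthetic cohort generator. Plants every structure the downstream stages
# are supposed to recover: regulator-driven sample clusters, a latent
# per-sample prognostic score driving two signature gene blocks and
# exponential survival, immune-cell gene blocks enriched per cluster,
# stromal/immune blocks tied to a latent microenvironment level, batch
# location/scale effects, tumor-vs-normal regulator shifts and logistic
# response labels. Gaussian log-expression throughout: all downstream
# statistics are rank- or linear-model-based, so this is the simplest
# structure every stage assumes.

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: 3 planted
#' clusters of 100 tumor samples each across 3 batches, 2000 genes, the 12
#' m5C regulators as clustering features with +/-1.5 SD cluster shifts,
#' two 60-gene signature blocks tied to a latent prognostic score, and
#' exponential survival (0.05 events/month baseline, 60-month uniform
#' censoring) whose log-hazard decreases by 0.8 per score SD.
#'
#' @param n_samples_per_cluster tumor samples per planted cluster.
#' @param n_clusters number of planted clusters (>= 2).
#' @param n_genes total gene universe size.
#' @param n_batches number of batches/cohorts.
#' @param regulator_names the 12 clustering feature genes (must be unique).
#' @param regulator_tumor_direction per-regulator tumor-vs-normal direction
#'   (+1 up in tumor, -1 down, 0 null).
#' @param cluster_shift magnitude (expression SD units) of the per-cluster
#'   regulator shifts.
#' @param batch_shift,batch_scale additive batch location effect (SD units,
#'   per-gene mean of the planted shifts) and multiplicative variance
#'   inflation applied to non-reference batches.
#' @param n_signature_A,n_signature_B sizes of the two signature blocks.
#' @param signature_coef expression shift per unit of the latent score z
#'   (+ for signature A genes, - for signature B genes).
#' @param immune_block_size,immune_shift per-cluster immune gene-block size
#'   and its up-shift within the matching cluster.
#' @param stromal_block_size,stromal_coef stromal and immune ESTIMATE-style
#'   block sizes and their slope on a latent microenvironment level w.
#' @param tumor_shift magnitude of the tumor-vs-normal regulator shift; the
#'   signature blocks get half this shift (A up, B down in tumors) so they
#'   are also tumor-vs-normal DEGs.
#' @param hazard_coef log-hazard decrease per unit z (> 0 means high z,
#'   hence high score, implies longer survival).
#' @param baseline_rate exponential event rate at z = 0 (events per month).
#' @param censor_horizon upper bound of uniform censoring (months).
#' @param noise_sd residual expression SD.
#' @param n_normal normal (non-tumor) samples per batch.
#' @param seed RNG seed; every generated cohort is a pure function of the
#'   config.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples_per_cluster = 100,
                       n_clusters = 3,
                       n_genes = 2000,
                       n_batches = 3,
                       regulator_names = m5c_regulators(),
                       regulator_tumor_direction = c(1, 1, -1, 1, 1, 0, 1, -1, -1, 0, 1, -1),
                       cluster_shift = 1.5,
                       batch_shift = 0.8,
                       batch_scale = 1.3,
                       n_signature_A = 60,
                       n_signature_B = 60,
                       signature_coef = 0.5,
                       immune_block_size = 30,
                       immune_shift = 1.0,
                       stromal_block_size = 30,
                       stromal_coef = 0.5,
                       tumor_shift = 1.0,
                       hazard_coef = 0.8,
                       baseline_rate = 0.05,
                       censor_horizon = 60,
                       noise_sd = 1.0,
                       n_normal = 10,
                       seed = 1) {
  cfg <- as.list(environment())
  check_count(cfg$n_samples_per_cluster, "n_samples_per_cluster")
  check_count(cfg$n_clusters, "n_clusters", min = 2)
  check_count(cfg$n_genes, "n_genes")
  check_count(cfg$n_batches, "n_batches")
  check_count(cfg$n_signature_A, "n_signature_A")
  check_count(cfg$n_signature_B, "n_signature_B")
  check_count(cfg$n_normal, "n_normal", min = 0)
  check_number(cfg$cluster_shift, "cluster_shift", min = 0)
  check_number(cfg$batch_shift, "batch_shift", min = 0)
  check_number(cfg$batch_scale, "batch_scale", min = 0)
  check_number(cfg$hazard_coef, "hazard_coef")
  check_number(cfg$baseline_rate, "baseline_rate", min = 1e-12)
  check_number(cfg$censor_horizon, "censor_horizon", min = 1e-12)
  check_number(cfg$noise_sd, "noise_sd", min = 1e-12)
  if (length(cfg$regulator_names) != 12L || anyDuplicated(cfg$regulator_names)) {
    stop2("regulator_names must be 12 unique gene identifiers")
  }
  if (length(cfg$regulator_tumor_direction) != 12L ||
      !all(cfg$regulator_tumor_direction %in% c(-1, 0, 1))) {
    stop2("regulator_tumor_direction must be 12 values in {-1, 0, 1}")
  }
  structure(cfg, class = "sim_config")
}

# Deterministic naming of the gene universe, shared between generate_cohort()
# and generate_gene_sets() so planted structure can be cross-referenced.
gene_universe <- function(config) {
  pad <- function(prefix, n) sprintf("%s_%03d", prefix, seq_len(n))
  sigA <- pad("SIGA", config$n_signature_A)
  sigB <- pad("SIGB", config$n_signature_B)
  overlapA <- intersect(sigA, config$regulator_names)
  overlapB <- intersect(sigB, config$regulator_names)
  if (length(overlapA) || length(overlapB)) {
    stop2("signature blocks collide with regulators: ",
          paste(c(overlapA, overlapB), collapse = ", "))
  }
  immune_blocks <- lapply(seq_len(config$n_clusters), function(c)
    sprintf("IMMC%d_%03d", c, seq_len(config$immune_block_size)))
  stromal <- pad("STRO", config$stromal_block_size)
  immune_est <- pad("IMME", config$stromal_block_size)
  core <- c(config$regulator_names, sigA, sigB, unlist(immune_blocks),
            stromal, immune_est)
  if (config$n_genes < length(core)) {
    stop2("n_genes (", config$n_genes, ") smaller than the structured blocks (",
          length(core), ")")
  }
  filler <- sprintf("GENE_%04d", seq_len(config$n_genes - length(core)))
  list(regulators = config$regulator_names, signature_A = sigA,
       signature_B = sigB, immune_blocks = immune_blocks,
       stromal = stromal, immune_est = immune_est, filler = filler,
       all = c(core, filler))
}

# A deterministic, seed-reproducible +/-1 sign pattern, distinct per cluster.
regulator_sign_matrix <- function(n_clusters, n_reg) {
  repeat {
    s <- matrix(sample(c(-1, 1), n_clusters * n_reg, replace = TRUE),
                nrow = n_clusters)
    if (!anyDuplicated(apply(s, 1, paste, collapse = ""))) return(s)
  }
}

#' Generate a synthetic multi-batch tumor cohort with planted ground truth
#'
#' See [sim_config()] for the planted structure. Tumor samples are assigned
#' round-robin to clusters and batches (so cluster and batch are crossed);
#' the latent score z is Normal(cluster offset, 1) with offsets evenly
#' spaced in \[-1, 1\]; survival is exponential with rate
#' `baseline_rate * exp(-hazard_coef * z)` censored Uniform(0,
#' `censor_horizon`); responders (CR/PR) are drawn with probability
#' `plogis(z)`. Batch 1 is the reference; later batches receive gene-wise
#' additive shifts Normal(`+-batch_shift`, 0.1^2) (sign alternating by
#' batch) and residual variance inflation `batch_scale`.
#'
#' @param config a [sim_config()].
#' @return List of class `synthetic_cohort`: `expression` ([expr_matrix()]),
#'   `clinical` (data.frame) and `truth` (planted labels, gene blocks,
#'   latent scores, batch parameters, response probabilities).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  uni <- gene_universe(config)
  genes <- uni$all
  G <- length(genes)
  k <- config$n_clusters
  n_tumor <- config$n_samples_per_cluster * k
  n_norm <- config$n_normal * config$n_batches
  n <- n_tumor + n_norm

  tumor <- c(rep(TRUE, n_tumor), rep(FALSE, n_norm))
  cluster <- c(rep_len(seq_len(k), n_tumor), rep(NA_integer_, n_norm))
  # clusters cycle with period k while batches advance in blocks of k, so
  # cluster and batch are crossed (never confounded) for any k, n_batches
  batch <- c(((seq_len(n_tumor) - 1L) %/% k) %% config$n_batches + 1L,
             rep(seq_len(config$n_batches), each = config$n_normal))
  ids <- c(sprintf("T%04d", seq_len(n_tumor)), sprintf("N%04d", seq_len(n_norm)))

  gene_mean <- runif(G, 4, 10)
  names(gene_mean) <- genes
  X <- matrix(rnorm(G * n, mean = gene_mean, sd = config$noise_sd), nrow = G,
              dimnames = list(genes, ids))

  # cluster structure on regulators: distinct sign pattern per cluster,
  # centered per gene across clusters so the cluster structure does not
  # bleed into the tumor-vs-normal contrast
  signs <- regulator_sign_matrix(k, 12L)
  shifts <- sweep(signs, 2, colMeans(signs))
  for (c in seq_len(k)) {
    cols <- which(!is.na(cluster) & cluster == c)
    X[uni$regulators, cols] <- X[uni$regulators, cols] +
      config$cluster_shift * shifts[c, ]
  }

  # tumor-vs-normal shifts (regulators by direction; signatures half-shift)
  tcols <- which(tumor)
  X[uni$regulators, tcols] <- X[uni$regulators, tcols] +
    config$tumor_shift * config$regulator_tumor_direction
  X[uni$signature_A, tcols] <- X[uni$signature_A, tcols] + config$tumor_shift / 2
  X[uni$signature_B, tcols] <- X[uni$signature_B, tcols] - config$tumor_shift / 2

  # latent prognostic score z (tumor only) drives the signature blocks
  offsets <- seq(-1, 1, length.out = k)
  z <- rep(0, n)
  z[tcols] <- rnorm(n_tumor, mean = offsets[cluster[tcols]], sd = 1)
  names(z) <- ids
  X[uni$signature_A, tcols] <- X[uni$signature_A, tcols] +
    config$signature_coef * rep(z[tcols], each = length(uni$signature_A))
  X[uni$signature_B, tcols] <- X[uni$signature_B, tcols] -
    config$signature_coef * rep(z[tcols], each = length(uni$signature_B))

  # immune blocks: block c up-shifted in cluster c (tumor samples)
  for (c in seq_len(k)) {
    cols <- which(!is.na(cluster) & cluster == c)
    X[uni$immune_blocks[[c]], cols] <- X[uni$immune_blocks[[c]], cols] +
      config$immune_shift
  }

  # stromal / immune ESTIMATE-style blocks follow a latent level w
  w <- rnorm(n)
  names(w) <- ids
  X[uni$stromal, ] <- X[uni$stromal, ] +
    config$stromal_coef * rep(w, each = length(uni$stromal))
  X[uni$immune_est, ] <- X[uni$immune_est, ] +
    config$stromal_coef * rep(w, each = length(uni$immune_est))

  # batch effects: batch 1 reference; others get additive gene-wise shift
  # with alternating sign and residual variance inflation
  delta <- matrix(0, G, config$n_batches, dimnames = list(genes, NULL))
  scale_fac <- rep(1, config$n_batches)
  if (config$n_batches > 1) {
    for (b in 2:config$n_batches) {
      dir_b <- c(1, -1)[(b %% 2) + 1L]  # b=2 -> +1, b=3 -> -1, ...
      delta[, b] <- rnorm(G, mean = dir_b * config$batch_shift, sd = 0.1)
      scale_fac[b] <- sqrt(config$batch_scale)
      cols <- which(batch == b)
      X[, cols] <- gene_mean + delta[, b] + scale_fac[b] * (X[, cols] - gene_mean)
    }
  }

  # survival: exponential with log-linear hazard in z; normals censored at
  # the horizon (they carry no outcome of interest)
  os_time <- rep(config$censor_horizon, n)
  os_event <- rep(0L, n)
  rate <- config$baseline_rate * exp(-config$hazard_coef * z[tcols])
  T_true <- rexp(n_tumor, rate = rate)
  C <- runif(n_tumor, 0, config$censor_horizon)
  os_time[tcols] <- pmin(T_true, C)
  os_event[tcols] <- as.integer(T_true <= C)

  # response labels: responder (CR/PR) with probability plogis(z)
  response <- rep(NA_character_, n)
  p_resp <- plogis(z[tcols])
  responder <- rbinom(n_tumor, 1, p_resp) == 1
  response[tcols] <- ifelse(responder,
                            sample(c("CR", "PR"), n_tumor, TRUE, prob = c(0.3, 0.7)),
                            sample(c("SD", "PD"), n_tumor, TRUE, prob = c(0.5, 0.5)))

  expression <- expr_matrix(X, batch = paste0("B", batch), tumor = tumor)
  clinical <- data.frame(
    sample_id = ids, os_time = os_time, os_event = os_event, tumor = tumor,
    batch = paste0("B", batch), response = response, stringsAsFactors = FALSE)
  validate_clinical(clinical)

  truth <- list(
    cluster = setNames(cluster, ids),
    z = z,
    signature_A = uni$signature_A,
    signature_B = uni$signature_B,
    immune_blocks = uni$immune_blocks,
    stromal_genes = uni$stromal,
    immune_est_genes = uni$immune_est,
    regulator_signs = signs,
    regulator_cluster_shifts = config$cluster_shift * shifts,
    regulator_tumor_direction = setNames(config$regulator_tumor_direction,
                                         config$regulator_names),
    tumor_deg_genes = c(uni$regulators[config$regulator_tumor_direction != 0],
                        uni$signature_A, uni$signature_B),
    batch_delta = delta,
    batch_scale = scale_fac,
    microenv_level = w,
    response_prob = setNames(p_resp, ids[tcols]),
    latent_survival_time = setNames(T_true, ids[tcols]))

  structure(list(expression = expression, clinical = clinical, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort: ", sum(x$clinical$tumor), " tumor + ",
      sum(!x$clinical$tumor), " normal samples, ",
      nrow(x$expression$values), " genes, ",
      x$config$n_clusters, " planted clusters\n", sep = "")
  invisible(x)
}

# Default names for the 24 immune-cell signature sets.
IMMUNE_CELL_TYPES <- c(
  "B cells", "T cells", "CD8 T cells", "T helper cells", "Tcm", "Tem",
  "Tfh", "Tgd", "Th1 cells", "Th17 cells", "Th2 cells", "Treg",
  "NK cells", "NK CD56bright cells", "NK CD56dim cells", "DC", "aDC",
  "iDC", "pDC", "Macrophages", "Mast cells", "Neutrophils", "Eosinophils",
  "Cytotoxic cells")

#' Generate gene-set collections matched to a synthetic cohort
#'
#' Returns 24 immune-cell marker sets (the first `n_planted` drawn from the
#' cohort's cluster-enriched immune gene blocks, cycling over clusters, the
#' rest from unstructured genes), one stromal and one immune ESTIMATE-style
#' set drawn from the corresponding planted blocks, and `n_pathways`
#' unstructured pathway sets. Which sets are planted, and for which cluster,
#' is recorded in the `planted` element.
#'
#' @param config the [sim_config()] the cohort was generated from.
#' @param sets_per_collection number of immune-cell sets (default 24).
#' @param genes_per_set genes per set, sampled without replacement.
#' @param n_planted number of cluster-enriched immune sets.
#' @param n_pathways number of unstructured pathway sets.
#' @param seed RNG seed.
#' @return List with elements `immune`, `stromal`, `immune_est`, `pathways`
#'   (gene-set collections / character vectors) and `planted` (data.frame
#'   mapping planted set name to its enriched cluster).
#' @export
generate_gene_sets <- function(config = sim_config(), sets_per_collection = 24,
                               genes_per_set = 15, n_planted = 6,
                               n_pathways = 10, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  check_count(sets_per_collection, "sets_per_collection")
  check_count(genes_per_set, "genes_per_set", min = 2)
  check_count(n_planted, "n_planted", min = 0)
  uni <- gene_universe(config)
  if (genes_per_set > length(uni$all)) {
    stop2("genes_per_set (", genes_per_set, ") exceeds the gene universe (",
          length(uni$all), ")")
  }
  n_planted <- min(n_planted, sets_per_collection)
  if (n_planted > 0 && genes_per_set > config$immune_block_size) {
    stop2("genes_per_set exceeds the planted immune block size (",
          config$immune_block_size, ")")
  }
  set.seed(seed)
  background <- c(uni$filler, uni$signature_A, uni$signature_B)
  if (genes_per_set > length(background)) background <- uni$all

  set_names <- if (sets_per_collection <= length(IMMUNE_CELL_TYPES)) {
    IMMUNE_CELL_TYPES[seq_len(sets_per_collection)]
  } else {
    c(IMMUNE_CELL_TYPES,
      sprintf("Immune set %d", seq_len(sets_per_collection - length(IMMUNE_CELL_TYPES))))
  }
  planted_cluster <- integer(0)
  sets <- vector("list", sets_per_collection)
  for (i in seq_len(sets_per_collection)) {
    if (i <= n_planted) {
      cl <- ((i - 1L) %% config$n_clusters) + 1L
      planted_cluster[i] <- cl
      pool <- uni$immune_blocks[[cl]]
    } else {
      planted_cluster[i] <- NA_integer_
      pool <- background
    }
    sets[[i]] <- sample(pool, genes_per_set)
  }
  names(sets) <- set_names
  immune <- gene_set_collection(sets)

  stromal_set <- sample(uni$stromal, min(genes_per_set, length(uni$stromal)))
  immune_est_set <- sample(uni$immune_est, min(genes_per_set, length(uni$immune_est)))
  pathways <- gene_set_collection(setNames(
    lapply(seq_len(n_pathways), function(i) sample(background, genes_per_set)),
    sprintf("Pathway %02d", seq_len(n_pathways))))

  list(immune = immune, stromal = stromal_set, immune_est = immune_est_set,
       pathways = pathways,
       planted = data.frame(set = set_names[seq_len(n_planted)],
                            cluster = planted_cluster[seq_len(n_planted)],
                            stringsAsFactors = FALSE))
}

#' Generate a synthetic drug-sensitivity reference panel
#'
#' Cell-line expression is standard normal; each drug's log-IC50 is a sparse
#' linear combination of genes plus Normal(0, `noise_sd`^2) noise. The true
#' coefficient matrix is returned so downstream ridge prediction can be
#' validated. The default dimensions keep the regression overdetermined
#' (lines well above genes), as in real drug-sensitivity panels where
#' hundreds of cell lines are profiled on a restricted gene signature.
#'
#' @param n_lines number of cell lines (> `n_drugs`).
#' @param n_genes number of genes.
#' @param n_drugs number of drugs.
#' @param effect_sparsity fraction of genes with nonzero effect per drug,
#'   in (0, 1].
#' @param noise_sd residual SD of log-IC50.
#' @param seed RNG seed.
#' @param gene_names optional gene names (default `GENE_0001` style, matching
#'   the cohort filler genes so panel and cohort share genes).
#' @return List: `expression` (genes x lines matrix), `ic50` (lines x drugs
#'   matrix of log-IC50), `coefficients` (genes x drugs truth).
#' @export
generate_reference_panel <- function(n_lines = 300, n_genes = 100, n_drugs = 5,
                                     effect_sparsity = 0.1, noise_sd = 1,
                                     seed = 1, gene_names = NULL) {
  check_count(n_lines, "n_lines", min = 2)
  check_count(n_genes, "n_genes")
  check_count(n_drugs, "n_drugs")
  if (n_lines <= n_drugs) stop2("n_lines must exceed n_drugs")
  if (!is.numeric(effect_sparsity) || effect_sparsity <= 0 || effect_sparsity > 1) {
    stop2("effect_sparsity must lie in (0, 1]")
  }
  check_number(noise_sd, "noise_sd", min = 0)
  set.seed(seed)
  genes <- gene_names %||% sprintf("GENE_%04d", seq_len(n_genes))
  if (length(genes) != n_genes) stop2("gene_names length must equal n_genes")
  lines_id <- sprintf("CL%03d", seq_len(n_lines))
  drugs <- sprintf("Drug%02d", seq_len(n_drugs))
  X <- matrix(rnorm(n_genes * n_lines), nrow = n_genes,
              dimnames = list(genes, lines_id))
  n_eff <- max(1L, ceiling(effect_sparsity * n_genes))
  beta <- matrix(0, n_genes, n_drugs, dimnames = list(genes, drugs))
  for (d in seq_len(n_drugs)) {
    idx <- sample(n_genes, n_eff)
    b <- rnorm(n_eff)
    # fixed signal norm: every drug carries the same planted
    # signal-to-noise ratio (signal SD 3 against noise_sd)
    beta[idx, d] <- 3 * b / sqrt(sum(b^2))
  }
  ic50 <- t(X) %*% beta + matrix(rnorm(n_lines * n_drugs, sd = noise_sd),
                                 n_lines, n_drugs)
  dimnames(ic50) <- list(lines_id, drugs)
  list(expression = X, ic50 = ic50, coefficients = beta)
}
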