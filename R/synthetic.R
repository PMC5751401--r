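## Synthetic chemogenomics fixtures: clustered per-target fingerprint
## "scaffolds" with controllable separability, class sizes, imbalance and
## label noise, plus a score/label generator for the calibration harness.
## Fixtures are fingerprint-level (no real chemistry) for speed.

#' Configuration of the synthetic chemogenomics generator
#'
#' Each target owns a set of `scaffold_bits` fingerprint bits. An active
#' ligand of the target switches each scaffold bit on with probability
#' `1 - mutation_rate` and each off-scaffold bit on with probability
#' `background_rate`; decoys carry background bits only.
#' `cross_target_overlap` makes consecutive target pairs share that fraction
#' of their scaffold bits, which blurs the panel's target resolution (a dial
#' for degradation experiments).
#'
#' @param n_targets number of targets.
#' @param actives_per_target actives per target (scalar or length-2 range).
#' @param n_decoys number of decoy ligands with no activity record.
#' @param n_bits fingerprint length (default 2048).
#' @param scaffold_bits scaffold bits per target (default 50).
#' @param mutation_rate per-active probability that a scaffold bit is lost.
#' @param background_rate probability that an off-scaffold bit is on.
#' @param cross_target_overlap shared scaffold fraction within target pairs.
#' @param seed integer seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_targets = 20L, actives_per_target = 30L,
                             n_decoys = 2000L, n_bits = 2048L,
                             scaffold_bits = 50L, mutation_rate = 0.05,
                             background_rate = 0.01,
                             cross_target_overlap = 0, seed = 1L) {
  stopifnot(n_targets >= 1L, n_decoys >= 0L, scaffold_bits >= 1L,
            mutation_rate >= 0, mutation_rate <= 1,
            background_rate >= 0, background_rate <= 1,
            cross_target_overlap >= 0, cross_target_overlap <= 1)
  cfg <- structure(list(n_targets = as.integer(n_targets),
                        actives_per_target = as.integer(actives_per_target),
                        n_decoys = as.integer(n_decoys),
                        n_bits = as.integer(n_bits),
                        scaffold_bits = as.integer(scaffold_bits),
                        mutation_rate = mutation_rate,
                        background_rate = background_rate,
                        cross_target_overlap = cross_target_overlap,
                        seed = as.integer(seed)),
                   class = "synthetic_config")
  if (scaffold_budget(cfg) > cfg$n_bits)
    tf_error("tf_config_error",
             "scaffold bit budget exceeds fingerprint length")
  cfg
}

scaffold_budget <- function(cfg) {
  shared <- floor(cfg$cross_target_overlap * cfg$scaffold_bits)
  n_pairs <- cfg$n_targets %/% 2L
  n_single <- cfg$n_targets %% 2L
  n_pairs * (2L * cfg$scaffold_bits - shared) + n_single * cfg$scaffold_bits
}

assign_scaffolds <- function(cfg) {
  shared <- floor(cfg$cross_target_overlap * cfg$scaffold_bits)
  pool <- sample(cfg$n_bits)  # permuted bit indices; consumed sequentially
  take <- local({
    i <- 0L
    function(n) { i <<- i + n; pool[(i - n + 1L):i] }
  })
  scaffolds <- vector("list", cfg$n_targets)
  t <- 1L
  while (t <= cfg$n_targets) {
    if (t + 1L <= cfg$n_targets) {
      common <- if (shared > 0L) take(shared) else integer()
      scaffolds[[t]] <- c(common, take(cfg$scaffold_bits - shared))
      scaffolds[[t + 1L]] <- c(common, take(cfg$scaffold_bits - shared))
      t <- t + 2L
    } else {
      scaffolds[[t]] <- take(cfg$scaffold_bits)
      t <- t + 1L
    }
  }
  scaffolds
}

#' Generate a synthetic chemogenomics dataset
#'
#' Emits an activity table in the standard six-column dialect (the SMILES
#' column holds the placeholder `"*"`: fixtures are fingerprint-level and
#' carry their fingerprints in a companion matrix), the fingerprint matrix
#' of all ligands, and the ground-truth active pairs. Actives receive one
#' qualifying assay row each (type drawn from IC50/EC50/Ki/Kd, potency
#' log-uniform in 1 nM .. 9.9 uM, so the activity definition reconstructs
#' the intended positives exactly); decoys receive no record, matching the
#' missing-data semantics of public bioactivity tables. Deterministic under
#' the config seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `table` (activity data.frame), `fingerprints` (0/1
#'   matrix, rownames = ligand ids), `pairs` (ground-truth active pairs),
#'   `target_meta`, `scaffolds`, `config`.
#' @export
generate_chemogenomics <- function(config = synthetic_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    scaffolds <- assign_scaffolds(cfg)
    n_act <- if (length(cfg$actives_per_target) == 2L)
      sample(cfg$actives_per_target[1L]:cfg$actives_per_target[2L],
             cfg$n_targets, replace = TRUE)
    else rep(cfg$actives_per_target, cfg$n_targets)
    target_ids <- sprintf("T%03d", seq_len(cfg$n_targets))
    n_ligands <- sum(n_act) + cfg$n_decoys
    ligand_ids <- sprintf("L%05d", seq_len(n_ligands))
    fp <- matrix(0L, n_ligands, cfg$n_bits, dimnames = list(ligand_ids, NULL))
    rows <- vector("list", cfg$n_targets)
    li <- 0L
    for (t in seq_len(cfg$n_targets)) {
      idx <- li + seq_len(n_act[t]); li <- li + n_act[t]
      for (i in idx) {
        keep <- stats::runif(cfg$scaffold_bits) > cfg$mutation_rate
        fp[i, scaffolds[[t]][keep]] <- 1L
        bg <- which(stats::runif(cfg$n_bits) < cfg$background_rate)
        fp[i, setdiff(bg, scaffolds[[t]])] <- 1L
      }
      value_nM <- 10^stats::runif(n_act[t], 0, log10(9900))
      unit <- sample(c("nM", "uM"), n_act[t], replace = TRUE)
      rows[[t]] <- data.frame(
        ligand_id = ligand_ids[idx],
        smiles = "*",
        target_id = target_ids[t],
        assay_type = sample(ASSAY_TYPES, n_act[t], replace = TRUE),
        value = ifelse(unit == "uM", value_nM / 1e3, value_nM),
        unit = unit,
        stringsAsFactors = FALSE)
    }
    if (cfg$n_decoys > 0L)
      for (i in li + seq_len(cfg$n_decoys))
        fp[i, stats::runif(cfg$n_bits) < cfg$background_rate] <- 1L
    table <- do.call(rbind, rows)
    rownames(table) <- NULL
    classes <- c("enzyme", "kinase", "membrane receptor", "ion channel")
    list(table = table,
         fingerprints = fp,
         pairs = unique(table[, c("ligand_id", "target_id")]),
         target_meta = data.frame(
           target_id = target_ids,
           name = paste("synthetic target", seq_len(cfg$n_targets)),
           target_class = rep_len(classes, cfg$n_targets),
           stringsAsFactors = FALSE),
         scaffolds = scaffolds,
         config = cfg)
  })
}

#' Write a synthetic dataset to disk in the standard dialects
#'
#' @param cg a [generate_chemogenomics()] result.
#' @param dir destination directory.
#' @return paths of the written activity table, fingerprint container and
#'   target metadata.
#' @export
write_chemogenomics <- function(cg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(table = file.path(dir, "activity.csv"),
                fingerprints = file.path(dir, "fingerprints.rds"),
                target_meta = file.path(dir, "targets.csv"))
  utils::write.csv(cg$table, paths$table, row.names = FALSE)
  write_fingerprints(cg$fingerprints, paths$fingerprints)
  utils::write.csv(cg$target_meta, paths$target_meta, row.names = FALSE)
  paths
}

#' Generate score/label pairs from a known calibration sigmoid
#'
#' Emulates the screening score distribution: a point mass of zero scores
#' (zero-score pairs are always inactive) and log-uniform positive scores on
#' `10^log10_range`. Labels are Bernoulli draws whose conditional intensity
#' is chosen so that the cutoff-based cumulative estimator
#' ([estimate_probability_points()]) is unbiased for the generating sigmoid
#' `p(c) = 1/(1+exp(-(alpha*log10(c) + beta)))` at every cutoff inside the
#' score support: because that estimator averages over all pairs above a
#' cutoff, the pointwise label probability must be
#' `sigma(u) * (1 + alpha*(u - u_max)*(1 - sigma(u)))` with `u = log10(score)`,
#' solved from the survival equation (see the methods vignette); parameter
#' combinations for which that intensity leaves \[0, 1\] are rejected.
#'
#' @param n_pairs number of score/label pairs.
#' @param alpha,beta generating sigmoid parameters (slope on log10 score).
#' @param seed integer seed.
#' @param zero_mass fraction of pairs with score exactly 0 (default 0.5).
#' @param log10_range support of log10(score) for positive scores.
#' @return list with `scores`, `labels` (`"active"`/`"inactive"`), `alpha`,
#'   `beta`.
#' @export
generate_score_labels <- function(n_pairs, alpha, beta, seed = 1L,
                                  zero_mass = 0.5,
                                  log10_range = c(-1.5, 0)) {
  stopifnot(n_pairs >= 1L, zero_mass >= 0, zero_mass < 1,
            log10_range[1L] < log10_range[2L])
  if (alpha < 0)
    tf_error("tf_config_error", "alpha must be non-negative")
  u_max <- log10_range[2L]
  sigma <- function(u) 1 / (1 + exp(-(alpha * u + beta)))
  # conditional intensity lambda(u) with E[lambda | u > c] = sigma(c) for
  # uniform u on [u_min, u_max]: lambda(u) = sigma(u) + alpha*(u - u_max)*
  # sigma(u)*(1 - sigma(u))
  lambda <- function(u) sigma(u) * (1 + alpha * (u - u_max) * (1 - sigma(u)))
  grid <- seq(log10_range[1L], u_max, length.out = 512L)
  if (min(lambda(grid)) < 0 || max(lambda(grid)) > 1)
    tf_error("tf_config_error",
             "generating sigmoid is too steep for the score support (label intensity leaves [0,1])")
  with_seed(seed, {
    is_zero <- stats::runif(n_pairs) < zero_mass
    u <- stats::runif(n_pairs, log10_range[1L], u_max)
    scores <- ifelse(is_zero, 0, 10^u)
    p <- ifelse(is_zero, 0, lambda(u))
    labels <- ifelse(stats::runif(n_pairs) < p, "active", "inactive")
    list(scores = scores, labels = labels, alpha = alpha, beta = beta)
  })
}
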