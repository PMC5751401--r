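## Per-target random-forest models, the unified forest-vote score, and
## whole-panel screening. Forests are fitted with ranger; a model's score
## for a ligand is the fraction of trees whose predicted class is "active",
## so every score is a multiple of 1/n_trees.

PANEL_SCHEMA_VERSION <- 1L

fp_colnames <- function(n_bits) paste0("b", seq_len(n_bits))

#' Train one per-target random-forest model
#'
#' Fits `n_trees` classification trees on the fingerprints of the training
#' set, honouring per-instance weights (weighted bootstrap sampling, which
#' realises weight-based positive oversampling). Other forest
#' hyperparameters are the classification defaults: sqrt(n_features)
#' candidate features per split, unlimited depth, bootstrap on; they are
#' recorded in the model object.
#'
#' @param training_set a `training_set` from the sampling module.
#' @param fingerprints 0/1 matrix with rownames covering the training set's
#'   ligand ids.
#' @param n_trees number of trees (default 100).
#' @param seed integer seed for the forest (deterministic retraining).
#' @return a `target_model`.
#' @export
train_target_model <- function(training_set, fingerprints, n_trees = 100L,
                               seed = 1L) {
  stopifnot(inherits(training_set, "training_set"), n_trees >= 1L)
  if (length(unique(training_set$label)) < 2L)
    tf_error("tf_degenerate_error",
             sprintf("target %s: training set has a single class",
                     training_set$target_id))
  x <- fingerprints[training_set$ligand_id, , drop = FALSE]
  colnames(x) <- fp_colnames(ncol(x))
  forest <- ranger::ranger(
    x = x, y = training_set$label,
    num.trees = n_trees,
    case.weights = training_set$weight,
    seed = seed, num.threads = 1L,
    verbose = FALSE
  )
  structure(list(
    target_id = training_set$target_id,
    forest = forest,
    n_trees = as.integer(n_trees),
    n_bits = ncol(x),
    train_seed = as.integer(seed),
    hyperparameters = list(mtry = forest$mtry, max_depth = "unlimited",
                           bootstrap = TRUE),
    training_summary = list(
      n_positives = sum(training_set$label == "active"),
      n_negatives = sum(training_set$label == "inactive"),
      positive_weight = training_set$weight[1L]
    )
  ), class = "target_model")
}

#' Forest-vote score of ligands against one target model
#'
#' The score in \[0, 1\] is the proportion of trees that classify the query
#' as active (each tree votes its majority leaf class), hence an exact
#' multiple of `1/n_trees`.
#'
#' @param model a `target_model`.
#' @param fp a fingerprint vector, or a matrix of fingerprints (row-wise).
#' @return numeric score(s) in \[0, 1\].
#' @export
score_ligand <- function(model, fp) {
  fp <- rbind(fp)
  if (ncol(fp) != model$n_bits)
    tf_error("tf_dimension_error",
             sprintf("fingerprint length %d does not match model's %d",
                     ncol(fp), model$n_bits))
  colnames(fp) <- fp_colnames(ncol(fp))
  pred <- stats::predict(model$forest, data = fp, predict.all = TRUE,
                         num.threads = 1L, verbose = FALSE)$predictions
  # ranger encodes per-tree class predictions as integer level indices
  active_idx <- which(model$forest$forest$levels == "active")
  unname(rowMeans(pred == active_idx))
}

#' Screen a ligand set against the whole model panel
#'
#' @param models list of `target_model`s.
#' @param fingerprints matrix of query fingerprints (rownames = ligand ids).
#' @return a `score_matrix`: ligands x targets, columns sorted by target id,
#'   every entry a vote fraction in \[0, 1\].
#' @export
screen_panel <- function(models, fingerprints) {
  if (length(models) == 0L)
    tf_error("tf_precondition_error", "empty model list")
  fingerprints <- rbind(fingerprints)
  ids <- unname(vapply(models, `[[`, character(1), "target_id"))
  ord <- order(ids)
  scores <- vapply(models[ord], score_ligand, numeric(nrow(fingerprints)),
                   fp = fingerprints)
  scores <- matrix(scores, nrow = nrow(fingerprints),
                   dimnames = list(rownames(fingerprints), ids[ord]))
  structure(scores, class = c("score_matrix", class(scores)))
}

#' @export
print.score_matrix <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}

#' Build the full model panel from active pairs and fingerprints
#'
#' Runs dataset assembly, imbalance sampling and forest training for every
#' eligible target (dataset -> sampling -> forest per target).
#'
#' @param active_pairs data.frame from [select_actives()].
#' @param fingerprints ligand fingerprint matrix (universe).
#' @param config an [activity_config()].
#' @param sampling a [sampling_config()].
#' @param n_trees trees per forest.
#' @param seed global seed; per-target seeds are derived from it.
#' @param targets optional explicit target set (default: all eligible).
#' @param check_eligibility passed to [build_target_dataset()].
#' @return a `panel`: named list of models plus build metadata.
#' @export
build_panel <- function(active_pairs, fingerprints,
                        config = activity_config(),
                        sampling = sampling_config(),
                        n_trees = 100L, seed = 1L,
                        targets = NULL, check_eligibility = TRUE) {
  if (is.null(targets)) targets <- eligible_targets(active_pairs, config)
  if (length(targets) == 0L)
    tf_error("tf_degenerate_error", "no eligible target")
  sampling$seed <- as.integer(seed)
  models <- lapply(targets, function(tid) {
    ds <- build_target_dataset(tid, active_pairs, fingerprints, config,
                               check_eligibility = check_eligibility)
    ts <- apply_sampling(ds, sampling)
    m <- train_target_model(ts, fingerprints, n_trees = n_trees,
                            seed = derive_seed(seed, paste0("forest:", tid)))
    m$training_summary$n_excluded <- length(ds$excluded)
    m
  })
  names(models) <- targets
  structure(list(models = models,
                 n_trees = as.integer(n_trees),
                 n_bits = ncol(fingerprints),
                 seed = as.integer(seed),
                 config = config, sampling = sampling),
            class = "panel")
}

#' @export
print.panel <- function(x, ...) {
  cat(sprintf("<panel: %d target models, %d trees each, %d-bit fingerprints>\n",
              length(x$models), x$n_trees, x$n_bits))
  invisible(x)
}

panel_config_hash <- function(panel) {
  key <- jsonlite::toJSON(list(n_trees = panel$n_trees, n_bits = panel$n_bits,
                               seed = panel$seed,
                               config = unclass(panel$config),
                               sampling = unclass(panel$sampling)),
                          auto_unbox = TRUE)
  derive_seed(0L, as.character(key))
}

#' Persist / restore a trained panel
#'
#' The panel directory holds `manifest.json` (schema version, tree count,
#' seeds, config hash, per-target training summaries) and one serialized
#' model file per target. A reloaded panel reproduces bit-identical score
#' matrices.
#'
#' @param panel a `panel`.
#' @param path panel directory (created if needed).
#' @export
save_panel <- function(panel, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    schema_version = PANEL_SCHEMA_VERSION,
    n_trees = panel$n_trees, n_bits = panel$n_bits, seed = panel$seed,
    config = unclass(panel$config), sampling = unclass(panel$sampling),
    config_hash = panel_config_hash(panel),
    targets = names(panel$models),
    training_summary = lapply(panel$models, function(m) m$training_summary)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (tid in names(panel$models))
    saveRDS(panel$models[[tid]], file.path(path, paste0("model_", tid, ".rds")))
  invisible(path)
}

#' @rdname save_panel
#' @export
load_panel <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path))
    tf_error("tf_compat_error", paste("no panel manifest at", path))
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(as.integer(manifest$schema_version), PANEL_SCHEMA_VERSION))
    tf_error("tf_compat_error",
             paste("unsupported panel schema version:", manifest$schema_version))
  models <- lapply(manifest$targets, function(tid) {
    f <- file.path(path, paste0("model_", tid, ".rds"))
    if (!file.exists(f))
      tf_error("tf_compat_error", paste("missing model file for target", tid))
    readRDS(f)
  })
  names(models) <- manifest$targets
  cfg <- manifest$config
  structure(list(models = models,
                 n_trees = as.integer(manifest$n_trees),
                 n_bits = as.integer(manifest$n_bits),
                 seed = as.integer(manifest$seed),
                 config = activity_config(cfg$activity_threshold_nM,
                                          cfg$min_actives,
                                          if (is.null(cfg$tc_cutoff)) NA else cfg$tc_cutoff),
                 sampling = sampling_config(manifest$sampling$method,
                                            manifest$sampling$ratio,
                                            manifest$sampling$seed)),
            class = "panel")
}

#' Write a score matrix as CSV (ligand rows, target columns)
#'
#' @param scores a `score_matrix`.
#' @param path destination CSV.
#' @export
write_score_matrix <- function(scores, path) {
  df <- data.frame(ligand_id = rownames(scores),
                   as.data.frame(unclass(scores)), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
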