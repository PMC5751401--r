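## Class-imbalance handling: negative undersampling and weight-based
## positive oversampling at a configurable inactive/active ratio.

#' Sampling configuration
#'
#' @param method `"negative_undersampling"` or `"positive_oversampling"`.
#' @param ratio target inactive/active count ratio (default 1; the panel's
#'   benchmark setting).
#' @param seed integer global seed; each target derives its own child seed
#'   from it, so sampling is reproducible and independent across targets.
#' @return a `sampling_config` list.
#' @export
sampling_config <- function(method = c("positive_oversampling",
                                       "negative_undersampling"),
                            ratio = 1, seed = 1L) {
  method <- match.arg(method)
  stopifnot(ratio > 0)
  structure(list(method = method, ratio = ratio, seed = as.integer(seed)),
            class = "sampling_config")
}

sample_negatives <- function(dataset, config) {
  n_pos <- length(dataset$positives)
  n_neg_pool <- length(dataset$negatives)
  if (n_pos == 0L || n_neg_pool == 0L)
    tf_error("tf_degenerate_error",
             sprintf("target %s: need at least one positive and one negative",
                     dataset$target_id))
  n_take <- min(n_neg_pool, round(config$ratio * n_pos))
  n_take <- max(1L, n_take)
  with_seed(derive_seed(config$seed, dataset$target_id),
            sample(dataset$negatives, n_take))
}

make_training_set <- function(dataset, negatives, pos_weight) {
  structure(list(
    ligand_id = c(dataset$positives, negatives),
    label = factor(rep(c("active", "inactive"),
                       c(length(dataset$positives), length(negatives))),
                   levels = c("active", "inactive")),
    weight = c(rep(pos_weight, length(dataset$positives)),
               rep(1, length(negatives))),
    target_id = dataset$target_id
  ), class = "training_set")
}

#' Negative undersampling
#'
#' Randomly keeps a subset of the putative inactives (uniform, without
#' replacement) until the inactive/active ratio reaches `config$ratio` (or
#' the pool is exhausted). All instance weights are 1.
#'
#' @param dataset a [build_target_dataset()] result.
#' @param config a [sampling_config()].
#' @return a `training_set`: ligand ids, labels, and unit weights.
#' @export
negative_undersample <- function(dataset, config = sampling_config()) {
  make_training_set(dataset, sample_negatives(dataset, config), 1)
}

#' Positive oversampling by instance weights
#'
#' Negatives are sampled exactly as in [negative_undersample()]; each active
#' then receives weight `n_negatives / n_positives`, so the total active
#' weight equals the total inactive weight. Up-weighting replaces literal
#' replication of the actives for practicality.
#'
#' @inheritParams negative_undersample
#' @return a `training_set` with up-weighted positives.
#' @export
positive_oversample <- function(dataset, config = sampling_config()) {
  negs <- sample_negatives(dataset, config)
  make_training_set(dataset, negs,
                    length(negs) / length(dataset$positives))
}

#' @export
print.training_set <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("<training_set %s: %d active (w=%.3g), %d inactive>\n",
              x$target_id, tab[["active"]], x$weight[1L], tab[["inactive"]]))
  invisible(x)
}

apply_sampling <- function(dataset, config) {
  switch(config$method,
         negative_undersampling = negative_undersample(dataset, config),
         positive_oversampling = positive_oversample(dataset, config))
}
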