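## Five-fold cross-validation harness, ROC/AUC, mean-score ratios,
## recall@top-k target ranking, external-set construction, and the
## chi-squared comparison between pipeline variants.

#' Ligand-level five-fold split
#'
#' Partitions the active ligands uniformly at random into `n_folds` folds of
#' sizes differing by at most one. The split is at the ligand level: a
#' ligand active for several targets lands in one fold for all of them, so
#' no fold can leak a held-out ligand into training through another target.
#'
#' @param ligand_ids character vector of active ligand ids.
#' @param seed integer seed.
#' @param n_folds number of folds (default 5).
#' @return named integer vector ligand_id -> fold index in 0..(n_folds-1).
#' @export
five_fold_split <- function(ligand_ids, seed = 1L, n_folds = 5L) {
  ligand_ids <- unique(ligand_ids)
  if (length(ligand_ids) < n_folds)
    tf_error("tf_precondition_error",
             sprintf("need at least %d distinct ligands, got %d",
                     n_folds, length(ligand_ids)))
  shuffled <- with_seed(seed, sample(ligand_ids))
  folds <- rep(seq_len(n_folds) - 1L, length.out = length(shuffled))
  stats::setNames(folds, shuffled)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the score threshold through all observed values; tied scores are
#' grouped so the trapezoidal area equals the rank-sum (concordant-pair)
#' statistic with ties counted half.
#'
#' @param scores numeric scores, higher = more active.
#' @param labels factor/character with values `"active"` / `"inactive"`.
#' @return a `roc_curve` list: `thresholds` (descending), `fpr`, `tpr`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    tf_error("tf_dimension_error", "scores and labels lengths differ")
  pos <- labels == "active"
  P <- sum(pos); N <- sum(!pos)
  if (P == 0L || N == 0L)
    tf_error("tf_degenerate_error", "AUC undefined with a single class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp_end <- which(!duplicated(s, fromLast = TRUE)) # last row of each tie group
  tp <- cumsum(p)[grp_end]
  fp <- cumsum(!p)[grp_end]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, s[grp_end]), fpr = fpr, tpr = tpr,
                 auc = auc),
            class = "roc_curve")
}

#' Mean-score ratio between active and inactive ligands
#'
#' The discrimination diagnostic reported per target: mean active score over
#' mean inactive score. A zero inactive mean with a positive active mean
#' yields `Inf`; two zero means yield `NaN` (undefined).
#'
#' @param active_scores,inactive_scores non-empty numeric vectors.
#' @return list with `mean_active`, `mean_inactive`, `ratio`.
#' @export
mean_score_ratio <- function(active_scores, inactive_scores) {
  if (length(active_scores) == 0L || length(inactive_scores) == 0L)
    tf_error("tf_precondition_error", "empty score list")
  ma <- mean(active_scores); mi <- mean(inactive_scores)
  ratio <- if (mi == 0 && ma == 0) NaN else if (mi == 0) Inf else ma / mi
  list(mean_active = ma, mean_inactive = mi, ratio = ratio)
}

#' Rank candidate targets for one ligand
#'
#' Targets sorted by descending score, ties broken by ascending target id;
#' an optional class filter is applied before ranking. Asking for more
#' targets than survive the filter returns them all with a logged note.
#'
#' @param score_vector named numeric vector (names = target ids).
#' @param k number of top targets to return.
#' @param class_filter optional character vector of admissible target classes.
#' @param target_classes named character vector target_id -> class (required
#'   when `class_filter` is given).
#' @return character vector of the top-k target ids, best first.
#' @export
rank_targets <- function(score_vector, k, class_filter = NULL,
                         target_classes = NULL) {
  stopifnot(k >= 1L)
  if (!is.null(class_filter)) {
    if (is.null(target_classes))
      tf_error("tf_precondition_error",
               "class_filter requires target_classes")
    keep <- names(score_vector)[target_classes[names(score_vector)] %in% class_filter]
    score_vector <- score_vector[keep]
  }
  if (length(score_vector) == 0L)
    tf_error("tf_precondition_error", "no target left after class filter")
  if (k > length(score_vector)) {
    tf_log(sprintf("k = %d exceeds %d available targets; returning all",
                   k, length(score_vector)), verbose = FALSE)
    k <- length(score_vector)
  }
  ord <- order(-score_vector, names(score_vector))
  names(score_vector)[ord][seq_len(k)]
}

#' Recall at top-k over a score matrix
#'
#' A true (ligand, target) interaction counts as detected (TP) iff the
#' target ranks within the ligand's top k; recall = TP / (TP + FN).
#'
#' @param scores a ligands x targets `score_matrix`.
#' @param true_pairs data.frame with `ligand_id`, `target_id`.
#' @param k rank threshold.
#' @return recall in \[0, 1\] (attribute `tp`/`fn` carry the counts).
#' @export
recall_at_k <- function(scores, true_pairs, k) {
  true_pairs <- true_pairs[true_pairs$target_id %in% colnames(scores), ,
                           drop = FALSE]
  if (nrow(true_pairs) == 0L)
    tf_error("tf_degenerate_error", "no true pair to evaluate")
  if (!all(true_pairs$ligand_id %in% rownames(scores)))
    tf_error("tf_precondition_error", "true pair ligand missing from matrix")
  tp <- 0L
  for (lig in unique(true_pairs$ligand_id)) {
    topk <- rank_targets(scores[lig, ], k)
    tp <- tp + sum(true_pairs$target_id[true_pairs$ligand_id == lig] %in% topk)
  }
  fn <- nrow(true_pairs) - tp
  structure(tp / (tp + fn), tp = tp, fn = fn)
}

#' Pearson chi-squared comparison of two TP/FN splits
#'
#' Compares how many true interactions two pipeline variants recover at a
#' fixed rank threshold, as a 2x2 Pearson chi-squared test (1 df, no
#' continuity correction).
#'
#' @param tp_a,fn_a,tp_b,fn_b non-negative integer counts.
#' @return list with `chi2` and `p_value`.
#' @export
compare_methods_chi2 <- function(tp_a, fn_a, tp_b, fn_b) {
  tab <- matrix(c(tp_a, fn_a, tp_b, fn_b), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    tf_error("tf_degenerate_error", "degenerate 2x2 table (zero marginal)")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Mean nearest-neighbour Tanimoto among a target's actives
#'
#' @param fp fingerprint matrix of the target's active ligands.
#' @return mean over actives of the Tc to their nearest fellow active, or
#'   `NA` with fewer than two actives.
#' @export
intra_class_tc <- function(fp) {
  fp <- rbind(fp)
  if (nrow(fp) < 2L) return(NA_real_)
  tc <- tanimoto_matrix(fp, fp)
  diag(tc) <- -Inf
  mean(apply(tc, 1L, max))
}

#' Five-fold cross-validation of the whole panel
#'
#' For each fold: all target datasets are rebuilt from training-fold ligands
#' only (the Tanimoto exclusion re-run against training actives alone), the
#' panel is retrained, and the held-out ligands are screened against every
#' model. A held-out (ligand, target) pair is labelled positive iff it is a
#' known active pair; all other pairs of held-out ligands count as negative.
#'
#' @param active_pairs data.frame from [select_actives()].
#' @param fingerprints fingerprint matrix of the full ligand universe.
#' @param config an [activity_config()].
#' @param sampling a [sampling_config()].
#' @param n_trees trees per forest.
#' @param k_list rank thresholds for recall@k.
#' @param seed global seed.
#' @param n_folds number of folds (default 5).
#' @return a `cv_report`: `per_target` data.frame (auc, mean scores, ratio,
#'   class_size, intra_class_tc), `overall_auc` (pooled over all held-out
#'   pairs), `recall_at_k` (fold-averaged, named by k), `recall_counts`
#'   (summed TP/FN per k, for chi-squared comparisons), `folds`.
#' @export
run_cv_experiment <- function(active_pairs, fingerprints,
                              config = activity_config(),
                              sampling = sampling_config(),
                              n_trees = 100L,
                              k_list = c(1, 4, 8, 11, 33, 66, 88, 110),
                              seed = 1L, n_folds = 5L) {
  targets <- eligible_targets(active_pairs, config)
  if (length(targets) == 0L)
    tf_error("tf_degenerate_error", "no eligible target")
  pairs <- active_pairs[active_pairs$target_id %in% targets, , drop = FALSE]
  pairs <- pairs[pairs$ligand_id %in% rownames(fingerprints), , drop = FALSE]
  k_list <- k_list[k_list <= length(targets)]
  folds <- five_fold_split(unique(pairs$ligand_id),
                           derive_seed(seed, "cv_folds"), n_folds)

  pooled_scores <- list(); pooled_labels <- list()
  train_ligands <- vector("list", n_folds)
  per_target_auc <- matrix(NA_real_, length(targets), n_folds,
                           dimnames = list(targets, NULL))
  act_sum <- inact_sum <- act_n <- inact_n <-
    stats::setNames(numeric(length(targets)), targets)
  recall_folds <- matrix(NA_real_, n_folds, length(k_list))
  tp_counts <- fn_counts <- stats::setNames(integer(length(k_list)),
                                            as.character(k_list))

  for (f in seq_len(n_folds) - 1L) {
    test_ligands <- names(folds)[folds == f]
    train_fp <- fingerprints[setdiff(rownames(fingerprints), test_ligands), ,
                             drop = FALSE]
    train_pairs <- pairs[!pairs$ligand_id %in% test_ligands, , drop = FALSE]
    train_ligands[[f + 1L]] <- rownames(train_fp)
    trainable <- targets[targets %in% train_pairs$target_id]
    panel <- build_panel(train_pairs, train_fp, config, sampling,
                         n_trees = n_trees,
                         seed = derive_seed(seed, paste0("cv_fold_", f)),
                         targets = trainable, check_eligibility = FALSE)
    scores <- screen_panel(panel$models,
                           fingerprints[test_ligands, , drop = FALSE])
    test_pairs <- pairs[pairs$ligand_id %in% test_ligands, , drop = FALSE]
    pair_key <- paste(test_pairs$ligand_id, test_pairs$target_id)

    for (tid in colnames(scores)) {
      lab <- ifelse(paste(rownames(scores), tid) %in% pair_key,
                    "active", "inactive")
      s <- scores[, tid]
      if (length(unique(lab)) == 2L)
        per_target_auc[tid, f + 1L] <- roc_auc(s, lab)$auc
      act_sum[tid] <- act_sum[tid] + sum(s[lab == "active"])
      act_n[tid] <- act_n[tid] + sum(lab == "active")
      inact_sum[tid] <- inact_sum[tid] + sum(s[lab == "inactive"])
      inact_n[tid] <- inact_n[tid] + sum(lab == "inactive")
      pooled_scores[[paste(f, tid)]] <- s
      pooled_labels[[paste(f, tid)]] <- lab
    }
    for (j in seq_along(k_list)) {
      r <- recall_at_k(scores, test_pairs, k_list[j])
      recall_folds[f + 1L, j] <- as.numeric(r)
      tp_counts[j] <- tp_counts[j] + attr(r, "tp")
      fn_counts[j] <- fn_counts[j] + attr(r, "fn")
    }
  }

  mean_active <- ifelse(act_n > 0, act_sum / act_n, NA_real_)
  mean_inactive <- ifelse(inact_n > 0, inact_sum / inact_n, NA_real_)
  ratio <- ifelse(mean_inactive == 0 & mean_active == 0, NaN,
                  ifelse(mean_inactive == 0, Inf, mean_active / mean_inactive))
  class_size <- vapply(targets, function(tid)
    length(unique(pairs$ligand_id[pairs$target_id == tid])), integer(1))
  itc <- vapply(targets, function(tid) {
    ids <- unique(pairs$ligand_id[pairs$target_id == tid])
    intra_class_tc(fingerprints[ids, , drop = FALSE])
  }, numeric(1))

  overall <- roc_auc(unlist(pooled_scores, use.names = FALSE),
                     unlist(pooled_labels, use.names = FALSE))
  structure(list(
    per_target = data.frame(
      target_id = targets,
      auc = rowMeans(per_target_auc, na.rm = TRUE),
      mean_active_score = mean_active,
      mean_inactive_score = mean_inactive,
      score_ratio = ratio,
      class_size = class_size,
      intra_class_tc = itc,
      row.names = NULL),
    overall_auc = overall$auc,
    overall_roc = overall,
    recall_at_k = stats::setNames(colMeans(recall_folds), as.character(k_list)),
    recall_counts = data.frame(k = k_list, tp = as.integer(tp_counts),
                               fn = as.integer(fn_counts)),
    k_list = k_list,
    folds = folds,
    train_ligands = train_ligands
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %d targets, overall AUC %.3f>\n",
              nrow(x$per_target), x$overall_auc))
  cat("recall@k:", paste(sprintf("k=%s %.3f", names(x$recall_at_k),
                                 x$recall_at_k), collapse = ", "), "\n")
  invisible(x)
}

#' Construct an external validation set of novel ligands
#'
#' Keeps the new ligands that (i) are not fingerprint-identical to any
#' training ligand and (ii) have at least one active pair with a modelled
#' target, and reports the mean nearest-training Tanimoto of the kept set
#' (the difficulty statistic of the validation).
#'
#' @param train_fp training-universe fingerprint matrix.
#' @param new_fp fingerprint matrix of the candidate external ligands.
#' @param new_pairs active pairs of the external records.
#' @param modeled_targets character vector of panel target ids.
#' @return list with `ligand_ids`, `pairs`, `mean_nearest_tc`.
#' @export
build_external_set <- function(train_fp, new_fp, new_pairs, modeled_targets) {
  new_fp <- rbind(new_fp)
  train_keys <- apply(train_fp, 1L, paste, collapse = "")
  new_keys <- apply(new_fp, 1L, paste, collapse = "")
  novel <- rownames(new_fp)[!new_keys %in% train_keys]
  pairs <- new_pairs[new_pairs$target_id %in% modeled_targets &
                       new_pairs$ligand_id %in% novel, , drop = FALSE]
  keep <- unique(pairs$ligand_id)
  mean_tc <- if (length(keep)) {
    nn <- apply(tanimoto_matrix(new_fp[keep, , drop = FALSE], train_fp), 1L, max)
    mean(nn)
  } else NA_real_
  list(ligand_ids = keep, pairs = pairs, mean_nearest_tc = mean_tc)
}
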