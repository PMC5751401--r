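# ROC/AUC, ranking metrics, fold handling, chi-squared comparison.

test_that("five_fold_split balances folds, partitions, and is deterministic", {
  ids <- sprintf("L%02d", 1:10)
  f <- five_fold_split(ids, seed = 3)
  expect_setequal(names(f), ids)
  expect_true(all(table(f) == 2L))
  expect_identical(f, five_fold_split(ids, seed = 3))
  expect_false(identical(f, five_fold_split(ids, seed = 4)))
  # uneven sizes differ by at most one
  f2 <- five_fold_split(sprintf("L%02d", 1:13), seed = 1)
  expect_lte(diff(range(table(f2))), 1L)
  expect_error(five_fold_split(c("a", "b"), 1), class = "tf_precondition_error")
})

test_that("roc_auc matches hand-computed and degenerate cases", {
  r <- roc_auc(c(0.9, 0.8, 0.4, 0.2),
               c("active", "inactive", "active", "inactive"))
  expect_equal(r$auc, 0.75)  # 3 of 4 pos/neg pairs concordant
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(utils::tail(r$fpr, 1), 1); expect_equal(utils::tail(r$tpr, 1), 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  perfect <- roc_auc(c(1, 0.9, 0.1, 0), c("active", "active", "inactive", "inactive"))
  expect_equal(perfect$auc, 1)
  expect_error(roc_auc(1:3 / 3, rep("active", 3)), class = "tf_degenerate_error")
  # shuffled labels give chance-level AUC
  set.seed(5)
  s <- runif(2000); l <- sample(c("active", "inactive"), 2000, replace = TRUE)
  expect_lt(abs(roc_auc(s, l)$auc - 0.5), 0.05)
})

test_that("trapezoidal AUC equals the rank-sum concordance oracle with ties", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(10:500, 1)
    scores <- sample(seq(0, 1, by = 0.01), n, replace = TRUE)  # forces ties
    labels <- sample(c("active", "inactive"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("active", "inactive")
    expect_equal(roc_auc(scores, labels)$auc, auc_oracle(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("mean_score_ratio handles the zero-score sentinels", {
  r <- mean_score_ratio(c(0.5, 0.7), c(0.01, 0.03))
  expect_equal(r$ratio, 30)
  expect_identical(mean_score_ratio(c(0.5, 0.5), c(0, 0))$ratio, Inf)
  expect_true(is.nan(mean_score_ratio(c(0, 0), c(0, 0))$ratio))
  expect_equal(mean_score_ratio(0.4, 0.4)$ratio, 1)
  expect_error(mean_score_ratio(numeric(), 1), class = "tf_precondition_error")
})

test_that("rank_targets orders by score with id tie-break and class filter", {
  sv <- c(A = 0.9, B = 0.2, C = 0.9, D = 0.1)
  expect_identical(rank_targets(sv, 2), c("A", "C"))
  classes <- c(A = "kinase", B = "protease", C = "protease", D = "kinase")
  expect_identical(rank_targets(sv, 2, class_filter = "protease",
                                target_classes = classes), c("C", "B"))
  expect_identical(rank_targets(sv, 1), "A")
  expect_length(rank_targets(sv, 10), 4L)  # k beyond count returns all
  expect_error(rank_targets(sv, 2, class_filter = "gpcr",
                            target_classes = classes),
               class = "tf_precondition_error")
})

test_that("recall_at_k matches exhaustive enumeration and is monotone in k", {
  sm <- structure(c(0.9, 0.1, 0.5, 0.8, 0.2, 0.7), dim = c(1, 6),
                  dimnames = list("q", paste0("T", 1:6)))
  truth <- data.frame(ligand_id = "q", target_id = c("T1", "T6"))  # ranks 1 and 4
  expect_equal(as.numeric(recall_at_k(sm, truth, 2)), 0.5)
  expect_equal(as.numeric(recall_at_k(sm, truth, 6)), 1)
  set.seed(23)
  scores <- matrix(runif(20 * 30), 20, 30,
                   dimnames = list(sprintf("L%02d", 1:20), sprintf("T%02d", 1:30)))
  truth <- unique(data.frame(
    ligand_id = sample(rownames(scores), 40, replace = TRUE),
    target_id = sample(colnames(scores), 40, replace = TRUE)))
  prev <- 0
  for (k in c(1, 3, 7, 15, 30)) {
    # oracle: exhaustive rank check per pair
    tp <- sum(apply(truth, 1, function(p) {
      ord <- order(-scores[p[["ligand_id"]], ], colnames(scores))
      which(colnames(scores)[ord] == p[["target_id"]]) <= k
    }))
    got <- recall_at_k(scores, truth, k)
    expect_equal(as.numeric(got), tp / nrow(truth))
    expect_gte(as.numeric(got), prev)
    prev <- as.numeric(got)
  }
  expect_equal(as.numeric(recall_at_k(scores, truth, 30)), 1)
  expect_error(recall_at_k(scores, truth[0, ], 1), class = "tf_degenerate_error")
})

test_that("compare_methods_chi2 equals the closed 2x2 form", {
  even <- compare_methods_chi2(10, 10, 10, 10)
  expect_equal(even$chi2, 0); expect_equal(even$p_value, 1)
  r <- compare_methods_chi2(30, 10, 10, 30)
  # closed form n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  expect_equal(r$chi2, 80 * (30 * 30 - 10 * 10)^2 / (40 * 40 * 40 * 40))
  expect_equal(r$chi2, 20)
  expect_equal(r$p_value, stats::pchisq(20, df = 1, lower.tail = FALSE),
               tolerance = 1e-6)
  sym <- compare_methods_chi2(10, 30, 30, 10)
  expect_equal(sym$chi2, r$chi2)
  expect_error(compare_methods_chi2(0, 0, 5, 5), class = "tf_degenerate_error")
})

test_that("cross-validation on a small panel is leak-free and well-formed", {
  cg <- small_fixture()
  pairs <- select_actives(cg$table)
  cv <- run_cv_experiment(pairs, cg$fingerprints, n_trees = 50L,
                          k_list = c(1, 2, 4, 6), seed = 13)
  expect_s3_class(cv, "cv_report")
  expect_equal(nrow(cv$per_target), 6L)
  expect_true(all(cv$per_target$auc >= 0 & cv$per_target$auc <= 1))
  expect_true(all(cv$recall_at_k >= 0 & cv$recall_at_k <= 1))
  expect_true(all(diff(cv$recall_at_k) >= 0))  # monotone in k
  expect_true(all(cv$per_target$class_size == 14L))
  expect_true(all(cv$per_target$intra_class_tc > 0 &
                    cv$per_target$intra_class_tc <= 1))
  # zero leakage: each fold's held-out ligands are absent from its training universe
  for (f in 0:4) {
    held <- names(cv$folds)[cv$folds == f]
    expect_length(intersect(held, cv$train_ligands[[f + 1]]), 0L)
  }
  # folds partition the active ligands
  expect_setequal(names(cv$folds), unique(pairs$ligand_id))
})

test_that("external-set construction drops duplicates and unmodeled-only ligands", {
  train_fp <- rand_fp(10, bits = 32, seed = 1)
  new_fp <- rbind(train_fp[1, ],                      # duplicate of a training ligand
                  rand_fp(2, bits = 32, seed = 99))
  rownames(new_fp) <- c("dup", "novel1", "novel2")
  new_pairs <- data.frame(ligand_id = c("dup", "novel1", "novel2"),
                          target_id = c("T1", "T1", "T_unmodeled"))
  ext <- build_external_set(train_fp, new_fp, new_pairs,
                            modeled_targets = c("T1", "T2"))
  expect_identical(ext$ligand_ids, "novel1")
  expect_equal(nrow(ext$pairs), 1L)
  expect_true(ext$mean_nearest_tc >= 0 && ext$mean_nearest_tc <= 1)
})
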