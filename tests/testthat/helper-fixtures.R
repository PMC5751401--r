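# Shared fixtures, built in code and cached for the session so expensive
# objects (the full synthetic benchmark and its cross-validation) are
# computed once across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the benchmark fixture: 20 targets x 30 actives, disjoint scaffolds,
# mutation rate 0.05, 2000 decoys
full_fixture <- function() cached("full_cg", {
  generate_chemogenomics(synthetic_config(
    n_targets = 20L, actives_per_target = 30L, n_decoys = 2000L,
    mutation_rate = 0.05, cross_target_overlap = 0, seed = 5L))
})

full_cv <- function() cached("full_cv", {
  cg <- full_fixture()
  run_cv_experiment(select_actives(cg$table), cg$fingerprints,
                    seed = 9L, k_list = c(1, 4, 8, 11))
})

# a small fixture for cheap pipeline tests
small_fixture <- function(seed = 21L, overlap = 0) cached(
  paste0("small_cg_", seed, "_", overlap), {
    generate_chemogenomics(synthetic_config(
      n_targets = 6L, actives_per_target = 14L, n_decoys = 250L,
      cross_target_overlap = overlap, seed = seed))
  })

# random binary fingerprints
rand_fp <- function(n, bits = 64L, p = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rbinom(n * bits, 1L, p), n, bits,
         dimnames = list(sprintf("F%03d", seq_len(n)), NULL))
}

# a linearly separable toy: positives share a 50-bit scaffold absent from
# the background-only negatives
separable_toy <- function(n_pos = 15L, n_neg = 30L, bits = 512L, seed = 42L) {
  set.seed(seed)
  scaffold <- 1:50
  fp <- matrix(0L, n_pos + n_neg, bits)
  for (i in seq_len(n_pos)) {
    fp[i, scaffold] <- 1L
    fp[i, sample(51:bits, 5)] <- 1L
  }
  for (i in n_pos + seq_len(n_neg)) fp[i, sample(51:bits, 8)] <- 1L
  rownames(fp) <- c(sprintf("P%02d", seq_len(n_pos)),
                    sprintf("N%02d", seq_len(n_neg)))
  ds <- structure(list(target_id = "TOY",
                       positives = rownames(fp)[seq_len(n_pos)],
                       negatives = rownames(fp)[n_pos + seq_len(n_neg)],
                       excluded = character()),
                  class = "target_dataset")
  list(fp = fp, dataset = ds)
}

# brute-force concordance (rank-sum) AUC oracle: pairs with ties counted half
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == "active"]
  neg <- scores[labels == "inactive"]
  grid <- outer(pos, neg, "-")
  (sum(grid > 0) + 0.5 * sum(grid == 0)) / (length(pos) * length(neg))
}

# write a small activity table to a temp CSV
write_activity_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
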