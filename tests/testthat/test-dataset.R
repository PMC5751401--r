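# Bioactivity parsing, the activity definition, and per-target assembly.

toy_table <- function() data.frame(
  ligand_id = c("l1", "l2", "l3", "l4", "l5"),
  smiles = "*",
  target_id = c("T1", "T1", "T1", "T2", "T2"),
  assay_type = c("IC50", "Ki", "AC50", "Kd", "EC50"),
  value = c(5, 10, 1, 5000, -5),
  unit = c("uM", "uM", "uM", "nM", "nM"),
  stringsAsFactors = FALSE)

test_that("load_activity_table validates rows and reports drops", {
  path <- write_activity_csv(toy_table())
  suppressMessages(loaded <- load_activity_table(path))
  expect_equal(nrow(loaded$records), 3L)       # AC50 row and negative value dropped
  expect_equal(loaded$n_dropped, 2L)
  expect_setequal(loaded$ligands$ligand_id, c("l1", "l2", "l4"))
  expect_error(load_activity_table(tempfile()), class = "tf_io_error")
  bad <- toy_table(); names(bad)[1] <- "compound"
  err <- tryCatch(load_activity_table(write_activity_csv(bad)), error = identity)
  expect_s3_class(err, "tf_schema_error")
  expect_match(conditionMessage(err), "ligand_id")
})

test_that("unit conversion normalizes to nM and rejects unknown units", {
  expect_equal(convert_to_nM(5, "uM"), 5000)
  expect_equal(convert_to_nM(5, "µM"), 5000)  # micro sign spelling
  expect_equal(convert_to_nM(c(1, 2), c("mM", "M")), c(1e6, 2e9))
  err <- tryCatch(convert_to_nM(1, "mg/mL"), error = identity)
  expect_s3_class(err, "tf_unit_error")
  expect_match(conditionMessage(err), "mg/mL", fixed = TRUE)
})

test_that("the activity definition is strictly below 10 uM after conversion", {
  path <- write_activity_csv(toy_table())
  suppressMessages(loaded <- load_activity_table(path))
  pairs <- select_actives(loaded$records)
  # IC50 5 uM -> active; Ki exactly 10 uM -> not; Kd 5000 nM = 5 uM -> active
  expect_setequal(paste(pairs$ligand_id, pairs$target_id),
                  c("l1 T1", "l4 T2"))
})

test_that("select_actives uses the ANY rule and is order-independent", {
  rec <- data.frame(ligand_id = "l1", target_id = "T1",
                    assay_type = c("IC50", "Ki"),
                    value = c(50, 2), unit = "uM")
  expect_equal(nrow(select_actives(rec)), 1L)       # one qualifying assay suffices
  shuffled <- rec[2:1, ]
  expect_identical(select_actives(rec), select_actives(shuffled))
  # duplicated measurements do not duplicate pairs
  expect_identical(select_actives(rbind(rec, rec)), select_actives(rec))
})

test_that("eligible_targets applies the min-actives boundary", {
  pairs <- data.frame(
    ligand_id = c(sprintf("a%02d", 1:9), sprintf("b%02d", 1:10)),
    target_id = rep(c("T9", "T10"), c(9, 10)))
  expect_identical(eligible_targets(pairs), "T10")   # 9 actives excluded, 10 included
  expect_identical(eligible_targets(pairs[0, ]), character())
})

test_that("build_target_dataset partitions the universe and excludes by Tc", {
  # 8 ligands, 3 actives for T1; one inactive built at Tc 0.8 to an active
  fp <- matrix(0L, 8, 40, dimnames = list(paste0("L", 1:8), NULL))
  fp[1, 1:10] <- 1L; fp[2, 11:20] <- 1L; fp[3, 21:30] <- 1L  # actives
  fp[4, 1:8] <- 1L                                           # Tc 8/10 to L1
  fp[5, 31:34] <- 1L; fp[6, 35:38] <- 1L; fp[7, c(39, 40)] <- 1L; fp[8, 31] <- 1L
  pairs <- data.frame(ligand_id = c("L1", "L2", "L3"), target_id = "T1")
  cfg <- activity_config(min_actives = 3, tc_cutoff = 0.5)
  ds <- build_target_dataset("T1", pairs, fp, cfg)
  expect_identical(ds$excluded, "L4")
  expect_setequal(ds$negatives, c("L5", "L6", "L7", "L8"))
  expect_setequal(c(ds$positives, ds$negatives, ds$excluded), rownames(fp))
  # no exclusion filter: every non-active is a negative
  ds2 <- build_target_dataset("T1", pairs, fp,
                              activity_config(min_actives = 3, tc_cutoff = NA))
  expect_length(ds2$excluded, 0L)
  expect_setequal(ds2$negatives, paste0("L", 4:8))
  expect_error(build_target_dataset("T1", pairs, fp,
                                    activity_config(min_actives = 5)),
               class = "tf_precondition_error")
})

test_that("Tc exclusion grows monotonically as the cutoff drops and never touches actives", {
  cg <- small_fixture()
  pairs <- select_actives(cg$table)
  cuts <- c(0.8, 0.5, 0.2, 0.05)
  prev <- character()
  for (ct in cuts) {
    ds <- build_target_dataset("T001", pairs, cg$fingerprints,
                               activity_config(tc_cutoff = ct))
    expect_true(all(prev %in% ds$excluded))   # lower cutoff never shrinks exclusion
    expect_length(intersect(ds$positives, ds$negatives), 0L)
    expect_length(intersect(ds$positives, ds$excluded), 0L)
    expect_setequal(c(ds$positives, ds$negatives, ds$excluded),
                    rownames(cg$fingerprints))
    prev <- ds$excluded
  }
})
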