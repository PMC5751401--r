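## Bioactivity table parsing, active/eligibility definitions, and per-target
## positive/negative assembly with Tanimoto exclusion of ambiguous inactives.

ASSAY_TYPES <- c("IC50", "EC50", "Ki", "Kd")

# concentration units accepted, as multipliers to nM
UNIT_TO_NM <- c(nM = 1, uM = 1e3, mM = 1e6, M = 1e9)

normalize_unit <- function(unit) {
  u <- trimws(unit)
  u <- sub("^µ", "u", u)   # micro sign
  u <- sub("^μ", "u", u)   # greek mu
  key <- c(nm = "nM", um = "uM", mm = "mM", m = "M")[tolower(u)]
  unname(key)
}

#' Convert assay concentrations to nM
#'
#' Accepts nM, uM (also spelled with a micro sign), mM, and M; any other
#' unit raises an error naming it rather than converting silently.
#'
#' @param value numeric vector of measured values.
#' @param unit character vector of concentration units.
#' @return numeric vector of values in nM.
#' @export
convert_to_nM <- function(value, unit) {
  key <- normalize_unit(unit)
  bad <- is.na(key)
  if (any(bad))
    tf_error("tf_unit_error",
             paste("unknown concentration unit(s):",
                   paste(unique(unit[bad]), collapse = ", ")))
  unname(value * UNIT_TO_NM[key])
}

#' Activity-definition configuration
#'
#' @param activity_threshold_nM potency threshold in nM below which a
#'   measurement makes a ligand active for a target (default 10 uM = 1e4 nM;
#'   strictly-below comparison).
#' @param min_actives minimum number of distinct active ligands a target
#'   needs before a model is built for it (default 10).
#' @param tc_cutoff Tanimoto cutoff above which a putative inactive that is
#'   similar to a known active is excluded from the negatives (default 0.5);
#'   `NA` disables the exclusion filter.
#' @return an `activity_config` list.
#' @export
activity_config <- function(activity_threshold_nM = 1e4,
                            min_actives = 10L,
                            tc_cutoff = 0.5) {
  stopifnot(activity_threshold_nM > 0, min_actives >= 1L)
  if (!is.na(tc_cutoff)) stopifnot(tc_cutoff > 0, tc_cutoff <= 1)
  structure(list(activity_threshold_nM = activity_threshold_nM,
                 min_actives = as.integer(min_actives),
                 tc_cutoff = tc_cutoff),
            class = "activity_config")
}

#' Load and validate a bioactivity table
#'
#' Expects a CSV/TSV with header columns `ligand_id, smiles, target_id,
#' assay_type, value, unit`. Rows with assay types outside
#' IC50/EC50/Ki/Kd or non-positive values are dropped with a logged count.
#'
#' @param path path to the table (delimiter sniffed from the header line).
#' @return list with `records` (validated data.frame), `ligands`
#'   (data.frame ligand_id/smiles, unique), `n_dropped`.
#' @export
load_activity_table <- function(path) {
  if (!file.exists(path)) tf_error("tf_io_error", paste("no such file:", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  need <- c("ligand_id", "smiles", "target_id", "assay_type", "value", "unit")
  miss <- setdiff(need, names(df))
  if (length(miss))
    tf_error("tf_schema_error",
             paste("missing column(s):", paste(miss, collapse = ", ")))
  df$value <- suppressWarnings(as.numeric(df$value))
  ok <- df$assay_type %in% ASSAY_TYPES & !is.na(df$value) & df$value > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    tf_log(sprintf("dropped %d row(s) with unsupported assay type or non-positive value",
                   n_dropped))
  df <- df[ok, , drop = FALSE]
  ligands <- unique(df[, c("ligand_id", "smiles")])
  if (anyDuplicated(ligands$ligand_id))
    tf_error("tf_schema_error", "a ligand_id maps to more than one SMILES")
  list(records = df, ligands = ligands, n_dropped = n_dropped)
}

#' Select active ligand-target pairs
#'
#' A (ligand, target) pair is active iff at least one qualifying measurement
#' (IC50/EC50/Ki/Kd) is strictly below the activity threshold after unit
#' conversion. Measurements at exactly the threshold do not qualify.
#'
#' @param records validated activity records (see [load_activity_table()]).
#' @param config an [activity_config()].
#' @return data.frame of unique active `ligand_id`/`target_id` pairs.
#' @export
select_actives <- function(records, config = activity_config()) {
  if (nrow(records) == 0L)
    return(data.frame(ligand_id = character(), target_id = character()))
  nm <- convert_to_nM(records$value, records$unit)
  hit <- records[nm < config$activity_threshold_nM, c("ligand_id", "target_id")]
  hit <- unique(hit)
  rownames(hit) <- NULL
  hit
}

#' Targets eligible for modelling
#'
#' Targets with at least `min_actives` distinct active ligands, sorted by id.
#'
#' @param active_pairs data.frame from [select_actives()].
#' @param config an [activity_config()].
#' @return character vector of eligible target ids.
#' @export
eligible_targets <- function(active_pairs, config = activity_config()) {
  if (nrow(active_pairs) == 0L) return(character())
  counts <- table(active_pairs$target_id)
  sort(names(counts)[counts >= config$min_actives])
}

#' Assemble the per-target training dataset
#'
#' Positives are the target's active ligands; every other ligand of the
#' universe is a putative inactive. Putative inactives whose nearest-active
#' Tanimoto similarity exceeds `tc_cutoff` are excluded as ambiguous (they
#' may well be untested actives); with `tc_cutoff = NA` nothing is excluded.
#'
#' @param target_id the target to assemble.
#' @param active_pairs data.frame from [select_actives()].
#' @param fingerprints 0/1 matrix of ligand fingerprints, rownames = ligand
#'   ids; its rownames define the ligand universe.
#' @param config an [activity_config()].
#' @param check_eligibility verify the target meets `min_actives` (default
#'   TRUE; the CV harness disables this for fold-restricted rebuilds).
#' @return a `target_dataset` list with `positives`, `negatives`, `excluded`
#'   (ligand-id character vectors) and `target_id`.
#' @export
build_target_dataset <- function(target_id, active_pairs, fingerprints,
                                 config = activity_config(),
                                 check_eligibility = TRUE) {
  universe <- rownames(fingerprints)
  pos <- unique(active_pairs$ligand_id[active_pairs$target_id == target_id])
  pos <- intersect(universe, pos)
  if (check_eligibility && length(pos) < config$min_actives)
    tf_error("tf_precondition_error",
             sprintf("target %s has %d active(s), below min_actives = %d",
                     target_id, length(pos), config$min_actives))
  candidates <- setdiff(universe, pos)
  excluded <- character()
  if (!is.na(config$tc_cutoff) && length(candidates) && length(pos)) {
    tc <- tanimoto_matrix(fingerprints[candidates, , drop = FALSE],
                          fingerprints[pos, , drop = FALSE])
    nearest <- apply(tc, 1L, max)
    excluded <- candidates[nearest > config$tc_cutoff]
  }
  structure(list(target_id = target_id,
                 positives = pos,
                 negatives = setdiff(candidates, excluded),
                 excluded = excluded),
            class = "target_dataset")
}

#' @export
print.target_dataset <- function(x, ...) {
  cat(sprintf("<target_dataset %s: %d positives, %d negatives, %d excluded>\n",
              x$target_id, length(x$positives), length(x$negatives),
              length(x$excluded)))
  invisible(x)
}

#' Load target metadata
#'
#' CSV with columns `target_id, name, target_class`.
#'
#' @param path file path.
#' @return data.frame with unique target ids.
#' @export
load_target_meta <- function(path) {
  if (!file.exists(path)) tf_error("tf_io_error", paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("target_id", "name", "target_class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    tf_error("tf_schema_error",
             paste("missing column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(df$target_id))
    tf_error("tf_schema_error", "duplicate target_id in metadata")
  df
}
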