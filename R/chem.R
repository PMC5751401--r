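## Chemistry substrate: SMILES standardization, circular fingerprints,
## Tanimoto similarity. Molecular parsing and perception are delegated to
## OpenBabel through ChemmineOB; similarity algebra is vectorised here.

OB_FP_LEN <- 4096L  # native length of OpenBabel's hashed ECFP bit vector

ob_canonical <- function(smiles, neutralize = FALSE) {
  opts <- if (neutralize) data.frame(names = "neutralize", args = "") else NULL
  out <- suppressWarnings(
    if (is.null(opts)) ChemmineOB::convertFormat("SMI", "CAN", smiles)
    else ChemmineOB::convertFormat("SMI", "CAN", smiles, options = opts)
  )
  # OpenBabel appends "<TAB>title\n"; a failed parse yields an empty string
  sub("[\t\n ].*$", "", out)
}

heavy_atom_count <- function(smiles) {
  mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  formula <- ChemmineOB::prop_OB(mol[[1]])$formula
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?\\d*", formula))[[1]]
  n <- 0L
  for (tk in toks) {
    el <- gsub("\\d", "", tk)
    cnt <- gsub("\\D", "", tk)
    if (el != "H") n <- n + if (nzchar(cnt)) as.integer(cnt) else 1L
  }
  n
}

#' Standardize a SMILES string
#'
#' Applies a fixed standardization contract before fingerprinting: keep only
#' the largest fragment (by heavy-atom count, discarding salt counter-ions),
#' neutralize +1/-1 charges where chemically valid, drop explicit hydrogens,
#' and emit the canonical SMILES. Aromatic (mesomeric) forms are unified by
#' aromatization during canonicalization. The operation is idempotent:
#' standardizing its own output returns the same string.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of standardized canonical SMILES.
#' @examples
#' \dontrun{
#' standardize_smiles("CCO.[Na+].[Cl-]")  # -> "CCO"
#' }
#' @export
standardize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s))
      tf_error("tf_parse_error", "empty SMILES string", smiles = s)
    can <- ob_canonical(s)
    if (!nzchar(can))
      tf_error("tf_parse_error", sprintf("unparseable SMILES: '%s'", s), smiles = s)
    frags <- strsplit(can, ".", fixed = TRUE)[[1]]
    if (length(frags) > 1L) {
      sizes <- vapply(frags, heavy_atom_count, integer(1))
      can <- frags[[which.max(sizes)]]
    }
    out <- ob_canonical(can, neutralize = TRUE)
    if (!nzchar(out))
      tf_error("tf_parse_error", sprintf("standardization failed for '%s'", s), smiles = s)
    out
  }, character(1), USE.NAMES = FALSE)
}

#' Circular (ECFP-style) fingerprint of a standardized SMILES
#'
#' Extended-connectivity fingerprint of the given radius (default 2, i.e.
#' diameter 4), hashed by OpenBabel and folded by index modulo to `n_bits`
#' (default 2048). Deterministic, and invariant to the atom ordering of the
#' input because fingerprints are computed on the molecular graph.
#'
#' @param smiles_std standardized canonical SMILES (character vector).
#' @param radius circular neighbourhood radius (>= 1).
#' @param n_bits folded fingerprint length, between 64 and 4096.
#' @return for a single SMILES an integer 0/1 vector of length `n_bits`; for
#'   several, a matrix with one row per ligand.
#' @export
fingerprint <- function(smiles_std, radius = 2L, n_bits = 2048L) {
  stopifnot(radius >= 1L, n_bits >= 64L)
  if (n_bits > OB_FP_LEN)
    tf_error("tf_config_error", sprintf("n_bits must be <= %d", OB_FP_LEN))
  fpname <- paste0("ECFP", 2L * radius)
  rows <- lapply(smiles_std, function(s) {
    if (is.na(s) || !nzchar(s)) tf_error("tf_parse_error", "empty SMILES string")
    mol <- tryCatch(ChemmineOB::forEachMol("SMILES", s, identity),
                    error = function(e) NULL)
    if (is.null(mol) || length(mol) == 0L || !nzchar(ob_canonical(s)))
      tf_error("tf_parse_error", sprintf("unparseable SMILES: '%s'", s))
    raw <- as.integer(ChemmineOB::fingerprint_OB(mol, fpname))
    folded <- integer(n_bits)
    on_idx <- which(raw == 1L)
    if (length(on_idx)) folded[unique((on_idx - 1L) %% n_bits + 1L)] <- 1L
    folded
  })
  if (length(rows) == 1L) rows[[1]] else do.call(rbind, rows)
}

#' Tanimoto similarity between two binary fingerprints
#'
#' |on(a) & on(b)| / |on(a) | on(b)|. Two all-zero fingerprints are defined
#' as dissimilar (0): an empty fingerprint carries no evidence of similarity.
#'
#' @param a,b binary 0/1 vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    tf_error("tf_dimension_error", sprintf(
      "fingerprint lengths differ: %d vs %d", length(a), length(b)))
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) 0 else inter / uni
}

#' Pairwise Tanimoto matrix between two fingerprint sets
#'
#' @param A,B binary matrices, one fingerprint per row, equal column counts.
#' @return `nrow(A)` x `nrow(B)` matrix of Tanimoto similarities; all-zero
#'   against all-zero scores 0.
#' @export
tanimoto_matrix <- function(A, B) {
  A <- rbind(A); B <- rbind(B)
  if (ncol(A) != ncol(B))
    tf_error("tf_dimension_error", "fingerprint lengths differ")
  inter <- tcrossprod(A, B)
  uni <- outer(rowSums(A), rowSums(B), "+") - inter
  tc <- ifelse(uni == 0, 0, inter / uni)
  dimnames(tc) <- list(rownames(A), rownames(B))
  tc
}

#' Maximum Tanimoto similarity of a query to a set of active ligands
#'
#' @param query a binary fingerprint vector.
#' @param actives a matrix of active fingerprints (one per row).
#' @return the largest Tanimoto similarity between `query` and any active.
#' @export
nearest_active_tc <- function(query, actives) {
  actives <- rbind(actives)
  if (nrow(actives) == 0L)
    tf_error("tf_precondition_error", "empty active set")
  max(tanimoto_matrix(rbind(query), actives))
}

## SMILES file I/O (.smi dialect: "SMILES<TAB>ligand_id", one per line) ------

#' Read a SMILES file
#'
#' One record per line, `SMILES<TAB>ligand_id`; lines without an id get
#' sequential ids `L1, L2, ...`.
#'
#' @param path file path.
#' @return data.frame with columns `ligand_id`, `smiles`.
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) tf_error("tf_io_error", paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  data.frame(
    ligand_id = vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) >= 2L) parts[[i]][2L] else paste0("L", i), character(1)),
    smiles = vapply(parts, `[[`, character(1), 1L),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_smiles_file
#' @param df data.frame with `ligand_id` and `smiles` columns.
#' @export
write_smiles_file <- function(df, path) {
  writeLines(paste(df$smiles, df$ligand_id, sep = "\t"), path)
  invisible(path)
}

## fingerprint container (binary, run-time artifact) -------------------------

FP_CONTAINER_VERSION <- 1L

#' Persist / load a fingerprint matrix with its ligand-id index
#'
#' Stored as a compressed serialized container; `read_fingerprints` restores
#' the 0/1 matrix with ligand ids as row names.
#'
#' @param fp integer 0/1 matrix, rownames = ligand ids.
#' @param path destination file.
#' @export
write_fingerprints <- function(fp, path) {
  stopifnot(is.matrix(fp), !is.null(rownames(fp)))
  saveRDS(list(version = FP_CONTAINER_VERSION, ligand_ids = rownames(fp),
               n_bits = ncol(fp), bits = fp), path, compress = "gzip")
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) tf_error("tf_io_error", paste("no such file:", path))
  obj <- readRDS(path)
  if (!identical(obj$version, FP_CONTAINER_VERSION))
    tf_error("tf_compat_error", "unknown fingerprint container version")
  fp <- obj$bits
  rownames(fp) <- obj$ligand_ids
  fp
}
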