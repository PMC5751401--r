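#' @keywords internal
"_PACKAGE"

## condition helpers ---------------------------------------------------------

tf_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "tf_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

tf_log <- function(..., verbose = getOption("targetfisher.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[targetfisher] ", ...)
}

## seeds ---------------------------------------------------------------------

#' Derive a reproducible child seed from a global seed and a string key
#'
#' All stochastic steps (negative sampling, forest training) draw their seed
#' from the single global seed plus a stable key (usually the target id), so
#' adding or removing one target never perturbs the samples of the others.
#'
#' @param seed integer global seed.
#' @param key character scalar (e.g. a target id).
#' @return an integer seed in \[0, 2^31).
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.character(key), length(key) == 1L)
  m <- 2147480009  # prime below 2^31
  h <- as.numeric(seed %% m)
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% m
  as.integer(h)
}

# evaluate expr with a local RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
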