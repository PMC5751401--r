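## Score-to-probability calibration: cutoff-based probability estimation
## followed by a sigmoid fit in log10(score).

DEFAULT_CUTOFFS <- c(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.5, 0.7, 0.9)

#' Estimate interaction probabilities at score cutoffs
#'
#' For each cutoff, keeps the (ligand, target) pairs scoring strictly above
#' it and estimates the interaction probability as the active fraction among
#' them. Cutoffs above the maximum observed score retain no pair and are
#' dropped with a log note.
#'
#' @param scores numeric scores in \[0, 1\].
#' @param labels `"active"` / `"inactive"`, aligned with `scores`.
#' @param cutoffs score cutoffs in \[0, 1).
#' @return data.frame of calibration points: `cutoff`, `n_above`,
#'   `n_active_above`, `p_hat`.
#' @export
estimate_probability_points <- function(scores, labels,
                                        cutoffs = DEFAULT_CUTOFFS) {
  if (length(scores) != length(labels))
    tf_error("tf_dimension_error", "scores and labels lengths differ")
  stopifnot(all(cutoffs >= 0 & cutoffs < 1))
  pts <- lapply(cutoffs, function(ct) {
    above <- scores > ct
    n <- sum(above)
    if (n == 0L) return(NULL)
    na <- sum(labels[above] == "active")
    data.frame(cutoff = ct, n_above = n, n_active_above = na, p_hat = na / n)
  })
  dropped <- sum(vapply(pts, is.null, logical(1)))
  if (dropped > 0)
    tf_log(sprintf("dropped %d cutoff(s) with no pair above them", dropped),
           verbose = FALSE)
  out <- do.call(rbind, pts)
  if (is.null(out))
    out <- data.frame(cutoff = numeric(), n_above = integer(),
                      n_active_above = integer(), p_hat = numeric())
  out
}

sigmoid_log10 <- function(s, alpha, beta) 1 / (1 + exp(-(alpha * log10(s) + beta)))

#' Fit the sigmoid calibration curve in log10(score)
#'
#' Weighted least squares of `p_hat ~ 1/(1 + exp(-(alpha*log10(cutoff) +
#' beta)))` over the calibration points, weighting each point by `n_above`
#' (its binomial precision). A zero cutoff cannot enter the log transform
#' and is dropped before fitting; `alpha >= 0` is enforced so the fitted
#' mapping is monotone non-decreasing.
#'
#' @param points data.frame from [estimate_probability_points()].
#' @return a `calibration_model`: `alpha`, `beta`, `score_floor`, `points`,
#'   `rss`.
#' @export
fit_sigmoid <- function(points) {
  pts <- points[points$cutoff > 0, , drop = FALSE]
  if (nrow(pts) < 3L || length(unique(pts$cutoff)) < 3L)
    tf_error("tf_precondition_error",
             "need at least 3 calibration points with distinct positive cutoffs")
  x <- log10(pts$cutoff)
  # start from a clamped logit-linear regression
  p0 <- pmin(pmax(pts$p_hat, 1e-3), 1 - 1e-3)
  lin <- stats::lm(stats::qlogis(p0) ~ x, weights = pts$n_above)
  start <- list(alpha = max(0, unname(stats::coef(lin)[2L])),
                beta = unname(stats::coef(lin)[1L]))
  fit <- tryCatch(
    minpack.lm::nlsLM(p_hat ~ 1 / (1 + exp(-(alpha * x + beta))),
                      data = data.frame(p_hat = pts$p_hat, x = x),
                      start = start, weights = pts$n_above,
                      lower = c(alpha = 0, beta = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      tf_error("tf_fit_error",
               paste("sigmoid fit failed:", conditionMessage(e))))
  cf <- stats::coef(fit)
  structure(list(alpha = unname(cf["alpha"]), beta = unname(cf["beta"]),
                 score_floor = min(pts$cutoff),
                 points = points,
                 rss = sum(stats::resid(fit)^2)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model: p = 1/(1+exp(-(%.4g*log10(s) + %.4g)))>\n",
              x$alpha, x$beta))
  invisible(x)
}

#' Map a forest-vote score to an interaction probability
#'
#' A score of exactly 0 maps to probability 0 (most putative-inactive pairs
#' score 0 and carry no evidence of interaction); positive scores go through
#' the fitted sigmoid of log10(score). The mapping is monotone
#' non-decreasing on \[0, 1\].
#'
#' @param score numeric score(s) in \[0, 1\].
#' @param model a fitted `calibration_model`.
#' @return probability vector in \[0, 1\].
#' @export
score_to_probability <- function(score, model) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(score < 0 | score > 1))
    tf_error("tf_domain_error", "score outside [0, 1]")
  ifelse(score == 0, 0, sigmoid_log10(score, model$alpha, model$beta))
}

#' Serialize / restore a calibration model as JSON
#'
#' @param model a `calibration_model`.
#' @param path destination JSON file.
#' @export
save_calibration <- function(model, path) {
  jsonlite::write_json(list(alpha = model$alpha, beta = model$beta,
                            score_floor = model$score_floor,
                            rss = model$rss,
                            points = model$points),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  if (!file.exists(path)) tf_error("tf_io_error", paste("no such file:", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(alpha = obj$alpha, beta = obj$beta,
                 score_floor = obj$score_floor,
                 points = obj$points, rss = obj$rss),
            class = "calibration_model")
}
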