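#' Average per-fold strength models for external prediction
#'
#' Averages slopes, intercepts and training normalization parameters
#' across the discovery sample's cross-validation folds (one model per
#' left-out subject under LOOCV), yielding the single regression model
#' applied to an external validation sample.
#'
#' @param fold_models Either a list of [fit_strength_model()] objects or
#'   the `fold_models` matrix stored in a [cpm_loocv()] result (columns
#'   slope, intercept, strength_mean, strength_sd, score_mean, score_sd).
#' @param source_mask Logical edge mask (typically the discovery
#'   contributing network) used to compute validation strengths.
#' @return An object of class `averaged_model` with `mean_slope`,
#'   `mean_intercept`, `mean_strength_mean`, `mean_strength_sd`,
#'   `mean_score_mean`, `mean_score_sd`, `source_mask`,
#'   `n_models_averaged`.
#' @export
average_models <- function(fold_models, source_mask = NULL) {
  if (is.list(fold_models) && !is.data.frame(fold_models)) {
    if (length(fold_models) == 0) stop("empty model list")
    stopifnot(all(vapply(fold_models, inherits, logical(1), "strength_model")))
    M <- t(vapply(fold_models, function(m) {
      c(m$slope, m$intercept, m$strength_mean, m$strength_sd, m$score_mean, m$score_sd)
    }, numeric(6)))
    colnames(M) <- c("slope", "intercept", "strength_mean", "strength_sd",
                     "score_mean", "score_sd")
  } else {
    M <- as.matrix(fold_models)
    if (nrow(M) == 0) stop("empty model list")
  }
  mu <- colMeans(M)
  structure(list(
    mean_slope = unname(mu["slope"]),
    mean_intercept = unname(mu["intercept"]),
    mean_strength_mean = unname(mu["strength_mean"]),
    mean_strength_sd = unname(mu["strength_sd"]),
    mean_score_mean = unname(mu["score_mean"]),
    mean_score_sd = unname(mu["score_sd"]),
    source_mask = source_mask,
    n_models_averaged = nrow(M)
  ), class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, ...) {
  cat(sprintf("<averaged_model> %d folds averaged; slope %.4f, intercept %.4f; mask: %s edges\n",
              x$n_models_averaged, x$mean_slope, x$mean_intercept,
              if (is.null(x$source_mask)) "none" else sum(x$source_mask)))
  invisible(x)
}

#' Predict an external validation sample with an averaged discovery model
#'
#' Computes each validation subject's network strength over the discovery
#' edge mask, normalizes it with the averaged discovery training
#' parameters (or, optionally, with the validation sample's own
#' statistics), applies the averaged linear model, maps predictions back
#' to the discovery score scale, and correlates predicted with observed
#' scores. The correlation is scale-free, so a different questionnaire
#' range in the validation sample does not bias it.
#'
#' @param avg An [average_models()] result with a non-NULL `source_mask`.
#' @param validation_edge_matrix n x E matrix over the same edge space
#'   (same N, same vectorization) as the discovery sample.
#' @param validation_scores Observed scores of the validation subjects
#'   (length n >= 3).
#' @param confounds Optional validation-sample confound matrix for a
#'   partial-r evaluation.
#' @param normalization `"discovery"` (default: averaged training
#'   parameters) or `"validation"` (z-score strengths within the
#'   validation sample).
#' @return List with `predicted`, `r`, optional `partial_r`, and
#'   `strengths`.
#' @export
external_predict <- function(avg, validation_edge_matrix, validation_scores,
                             confounds = NULL,
                             normalization = c("discovery", "validation")) {
  stopifnot(inherits(avg, "averaged_model"))
  normalization <- match.arg(normalization)
  if (is.null(avg$source_mask)) stop("averaged model carries no source edge mask")
  X <- as.matrix(validation_edge_matrix)
  if (ncol(X) != length(avg$source_mask)) {
    stop(sprintf("edge-space mismatch: validation has %d edges, discovery mask %d",
                 ncol(X), length(avg$source_mask)))
  }
  n <- nrow(X)
  if (n < 3 || length(validation_scores) != n) {
    stop("need >= 3 aligned validation subjects (correlation undefined otherwise)")
  }
  s <- network_strength(X, avg$source_mask)
  if (normalization == "discovery") {
    zs <- (s - avg$mean_strength_mean) / avg$mean_strength_sd
  } else {
    if (stats::sd(s) == 0) stop("constant validation strengths; cannot self-normalize")
    zs <- (s - mean(s)) / stats::sd(s)
  }
  pred <- (avg$mean_intercept + avg$mean_slope * zs) * avg$mean_score_sd +
    avg$mean_score_mean
  perf <- evaluate_predictions(pred, validation_scores, confounds)
  c(list(predicted = pred, strengths = s), perf)
}
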