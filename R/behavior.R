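#' Exclude subjects by mean framewise displacement
#'
#' Head-motion exclusion: subjects whose mean FD strictly exceeds the
#' threshold are removed (a subject at exactly the threshold is
#' retained).
#'
#' @param records data.frame with `subject_id` and `mean_fd` columns.
#' @param threshold Exclusion threshold in mm (default 0.3).
#' @return List with `retained` (filtered data.frame) and `excluded`
#'   (character vector of excluded subject ids).
#' @export
filter_by_motion <- function(records, threshold = 0.3) {
  if (!"mean_fd" %in% names(records)) stop("records need a 'mean_fd' column")
  if (any(is.na(records$mean_fd))) {
    stop(sprintf("missing mean_fd for subject(s): %s",
                 paste(records$subject_id[is.na(records$mean_fd)], collapse = ", ")))
  }
  keep <- records$mean_fd <= threshold
  retained <- records[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, excluded = records$subject_id[!keep])
}

#' The five negative-emotion subscale names
#' @return Character vector: state anxiety, depression, perceived stress,
#'   negative affect, loneliness.
#' @export
emotion_subscales <- function() {
  c("state_anxiety", "depression", "perceived_stress",
    "negative_affect", "loneliness")
}

#' Impute missing subscale values
#'
#' Completes a subject-by-subscale panel. Two strategies ship with the
#' package: `"mean"` (column-mean baseline) and `"rf"` (the default, an
#' iterative tree-ensemble scheme: missing cells are initialized at the
#' column mean, then each incomplete column is repeatedly re-predicted
#' from the others with a random forest until the imputed values
#' stabilize). A custom strategy may be supplied as a function
#' `(panel, missing_index) -> completed panel`. Observed values are never
#' altered, and the result is deterministic given `seed`.
#'
#' @param panel data.frame or matrix of numeric subscale columns; NA
#'   marks missing cells.
#' @param strategy `"rf"`, `"mean"`, or a function.
#' @param seed Integer seed (default 1).
#' @param max_iter Maximum sweeps of the iterative scheme (default 10).
#' @param ntree Trees per forest (default 100).
#' @return Completed panel, same shape and class as the input.
#' @export
impute_missing <- function(panel, strategy = c("rf", "mean"), seed = 1L,
                           max_iter = 10L, ntree = 100L) {
  was_df <- is.data.frame(panel)
  M <- as.matrix(panel)
  if (!is.numeric(M)) stop("panel must be numeric")
  miss <- is.na(M)
  n_obs <- colSums(!miss)
  if (any(n_obs == 0)) {
    stop(sprintf("subscale(s) with no observed values: %s",
                 paste(colnames(M)[n_obs == 0], collapse = ", ")))
  }
  if (any(n_obs < 2)) stop("need >= 2 observed values per subscale to impute")
  if (!any(miss)) return(panel)

  if (is.function(strategy)) {
    out <- strategy(panel, miss)
    return(out)
  }
  strategy <- match.arg(strategy)
  col_means <- colMeans(M, na.rm = TRUE)
  for (j in seq_len(ncol(M))) M[miss[, j], j] <- col_means[j]
  if (strategy == "mean") {
    res <- M
  } else {
    res <- with_seed(seed, {
      prev <- M
      for (it in seq_len(max_iter)) {
        # visit columns by ascending missingness, as iterative imputers do
        for (j in order(colSums(miss))) {
          if (!any(miss[, j])) next
          fit <- randomForest::randomForest(
            x = prev[!miss[, j], -j, drop = FALSE],
            y = prev[!miss[, j], j],
            ntree = ntree
          )
          prev[miss[, j], j] <- stats::predict(fit, prev[miss[, j], -j, drop = FALSE])
        }
        delta <- sum((prev[miss] - M[miss])^2) / max(sum(M[miss]^2), .Machine$double.eps)
        if (delta < 1e-6) { M <- prev; break }
        M <- prev
      }
      M
    })
  }
  if (was_df) {
    out <- as.data.frame(res)
    names(out) <- names(panel)
    out
  } else res
}

#' Principal-component negative-emotion composite
#'
#' Standardizes each of the five subscales to z-scores, extracts the
#' first principal component of their correlation matrix, scales the
#' eigenvector so each loading equals the component's correlation with
#' its subscale (eigenvector times the square root of the eigenvalue,
#' oriented so the loading sum is positive), and forms the per-subject
#' composite as the sum of the products of the standard scores and their
#' loadings. A warning is issued if the first eigenvalue is <= 1 or a
#' second eigenvalue exceeds 1 (a one-factor structure is expected).
#'
#' @param panel Complete numeric data.frame/matrix of the five subscales
#'   (no missing values, each with nonzero variance). Any number of
#'   columns >= 2 is accepted; five is the standard panel.
#' @return List of class `composite_result`: `loadings`, `eigenvalue`,
#'   `variance_explained` (percent), `composite` (per-subject,
#'   mean-zero), `z_scores`.
#' @export
negative_emotion_composite <- function(panel) {
  M <- as.matrix(panel)
  if (any(is.na(M))) stop("panel has missing values; impute first")
  if (ncol(M) < 2) stop("need at least two subscales")
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance subscale(s): %s",
                 paste(colnames(M)[sds == 0], collapse = ", ")))
  }
  Z <- scale(M)
  R <- stats::cor(M)
  ev <- eigen(R, symmetric = TRUE)
  lambda <- ev$values[1]
  v <- ev$vectors[, 1]
  loadings <- v * sqrt(lambda)
  if (sum(loadings) < 0) loadings <- -loadings
  names(loadings) <- colnames(M)
  if (lambda <= 1) warning("first eigenvalue <= 1; subscales barely share a common factor")
  if (ncol(M) > 1 && ev$values[2] > 1) {
    warning("second eigenvalue > 1; more than one factor may be present")
  }
  composite <- drop(Z %*% loadings)
  structure(list(
    loadings = loadings,
    eigenvalue = lambda,
    variance_explained = 100 * lambda / ncol(M),
    composite = composite,
    z_scores = Z
  ), class = "composite_result")
}

#' @export
print.composite_result <- function(x, ...) {
  cat(sprintf("<composite_result> eigenvalue %.3f (%.2f%% variance)\n",
              x$eigenvalue, x$variance_explained))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Combine standard scores with fixed loadings
#'
#' The composite combination rule in isolation: the sum of the products
#' of given standard scores and factor loadings. Exposed so externally
#' reported loadings can be applied to new subjects.
#'
#' @param z_scores Vector (one subject) or matrix (subjects x subscales)
#'   of standard scores.
#' @param loadings Factor loadings, aligned with the subscales.
#' @return Composite score(s).
#' @export
composite_from_loadings <- function(z_scores, loadings) {
  if (is.matrix(z_scores)) {
    if (ncol(z_scores) != length(loadings)) stop("loadings must align with columns")
    drop(z_scores %*% loadings)
  } else {
    if (length(z_scores) != length(loadings)) stop("loadings must align with scores")
    sum(z_scores * loadings)
  }
}
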