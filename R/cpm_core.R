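#' Correlate every edge with a behavioral score
#'
#' Computes the per-edge Pearson correlation with the target (and a
#' two-sided p-value from the t distribution), or the partial Pearson
#' correlation when confounds are supplied. Partial correlations are
#' obtained by residualizing both the edge and the score on the confounds
#' (with intercept); p-values then use n - 2 - C degrees of freedom.
#'
#' Zero-variance edges receive r = 0 and p = 1 (they can never be
#' selected); their count is attached as attribute `n_zero_variance`.
#'
#' @param edge_matrix n x E numeric matrix (subjects by edges).
#' @param scores Length-n numeric target vector (nonconstant).
#' @param confounds Optional n x C numeric matrix of confounds.
#' @return List with `r`, `p` (length E) and `df` (scalar residual df).
#' @export
correlate_edges <- function(edge_matrix, scores, confounds = NULL) {
  X <- as.matrix(edge_matrix)
  y <- as.numeric(scores)
  n <- nrow(X)
  C <- if (is.null(confounds)) 0L else ncol(as.matrix(confounds))
  if (length(y) != n) stop("scores length must match edge_matrix rows")
  if (n <= C + 3) stop("insufficient sample for selection (need n > confounds + 3)")
  if (stats::sd(y) == 0) stop("scores are constant; correlation undefined")
  if (C > 0) {
    Z <- cbind(1, as.matrix(confounds))
    qz <- qr(Z)
    X <- qr.resid(qz, X)
    y <- qr.resid(qz, y)
  } else {
    X <- sweep(X, 2, colMeans(X))
    y <- y - mean(y)
  }
  sy <- sqrt(sum(y^2))
  sx <- sqrt(colSums(X^2))
  zero_var <- sx <= 0
  r <- as.vector(crossprod(X, y)) / (sx * sy)
  r[zero_var] <- 0
  r <- pmin(1, pmax(-1, r))
  df <- n - 2L - C
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.xmin))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  p[zero_var] <- 1
  out <- list(r = r, p = p, df = df)
  attr(out, "n_zero_variance") <- sum(zero_var)
  out
}

#' Split correlated edges into positive and negative networks
#'
#' Selects edges with strictly `p < threshold` and partitions them by the
#' sign of the correlation. Edges with r = 0 are never selected, so the
#' two masks are always disjoint.
#'
#' @param edge_r Per-edge correlations.
#' @param edge_p Per-edge two-sided p-values.
#' @param threshold Selection threshold (default 0.01).
#' @return An object of class `edge_selection` with `pos_mask`,
#'   `neg_mask`, `edge_r`, `edge_p`, `threshold`.
#' @export
select_edges <- function(edge_r, edge_p, threshold = 0.01) {
  if (length(edge_r) != length(edge_p)) stop("edge_r and edge_p must be aligned")
  sig <- edge_p < threshold
  structure(list(
    pos_mask = sig & edge_r > 0,
    neg_mask = sig & edge_r < 0,
    edge_r = edge_r,
    edge_p = edge_p,
    threshold = threshold
  ), class = "edge_selection")
}

#' @export
print.edge_selection <- function(x, ...) {
  cat(sprintf("<edge_selection> p < %g: %d positive, %d negative of %d edges\n",
              x$threshold, sum(x$pos_mask), sum(x$neg_mask), length(x$edge_r)))
  invisible(x)
}

#' Network strength: summed selected edges
#'
#' @param edge_values Either a length-E vector (one subject) or an n x E
#'   matrix.
#' @param mask Logical vector over edges.
#' @return Scalar (vector input) or length-n vector (matrix input); an
#'   empty mask yields 0.
#' @export
network_strength <- function(edge_values, mask) {
  if (is.matrix(edge_values)) {
    if (ncol(edge_values) != length(mask)) stop("mask length must match edge count")
    return(rowSums(edge_values[, mask, drop = FALSE]))
  }
  if (length(edge_values) != length(mask)) stop("mask length must match edge count")
  sum(edge_values[mask])
}

#' Fit the normalized strength-score linear model
#'
#' Both strength and score are z-scored with training mean and (n-1) sd;
#' an ordinary least-squares line of normalized score on normalized
#' strength is fit. The training normalization parameters are stored so
#' held-out subjects can be normalized identically. Constant strengths
#' yield a documented degenerate model (slope 0) predicting the training
#' mean score.
#'
#' @param strengths Per-training-subject network strength.
#' @param scores Per-training-subject observed score (nonconstant).
#' @return An object of class `strength_model`: `slope`, `intercept`
#'   (normalized space), `strength_mean`, `strength_sd`, `score_mean`,
#'   `score_sd`, `degenerate`.
#' @export
fit_strength_model <- function(strengths, scores) {
  s <- as.numeric(strengths); y <- as.numeric(scores)
  if (length(s) != length(y)) stop("strengths and scores must be aligned")
  if (length(s) < 3) stop("need at least 3 training subjects")
  y_mean <- mean(y); y_sd <- stats::sd(y)
  if (y_sd == 0) stop("training scores are constant; model undefined")
  s_mean <- mean(s); s_sd <- stats::sd(s)
  if (s_sd == 0) {
    warning("constant training strengths; degenerate model predicts the training mean score")
    return(structure(list(slope = 0, intercept = 0,
                          strength_mean = s_mean, strength_sd = 1,
                          score_mean = y_mean, score_sd = y_sd,
                          degenerate = TRUE), class = "strength_model"))
  }
  zs <- (s - s_mean) / s_sd
  zy <- (y - y_mean) / y_sd
  slope <- sum((zs - mean(zs)) * zy) / sum((zs - mean(zs))^2)
  intercept <- mean(zy) - slope * mean(zs)
  structure(list(slope = slope, intercept = intercept,
                 strength_mean = s_mean, strength_sd = s_sd,
                 score_mean = y_mean, score_sd = y_sd,
                 degenerate = FALSE), class = "strength_model")
}

#' Predict a raw-scale score from a raw network strength
#'
#' Normalizes the held-out strength with the training parameters, applies
#' the normalized-space linear model, and maps the prediction back to the
#' raw score scale with the training score mean/sd.
#'
#' @param model A [fit_strength_model()] result.
#' @param strength Raw strength value(s) of held-out subject(s).
#' @return Predicted score(s) on the raw scale.
#' @export
predict_score <- function(model, strength) {
  stopifnot(inherits(model, "strength_model"))
  if (model$degenerate) return(rep(model$score_mean, length(strength)))
  zs <- (strength - model$strength_mean) / model$strength_sd
  (model$intercept + model$slope * zs) * model$score_sd + model$score_mean
}

#' Evaluate out-of-fold predictions
#'
#' Pearson correlation between predicted and observed scores, plus the
#' partial correlation controlling confounds when supplied (both vectors
#' residualized on the confounds with intercept).
#'
#' @param predicted,observed Aligned numeric vectors.
#' @param confounds Optional n x C confound matrix.
#' @return List with `r` and (when confounds given) `partial_r`.
#' @export
evaluate_predictions <- function(predicted, observed, confounds = NULL) {
  if (length(predicted) != length(observed)) stop("predicted and observed must be aligned")
  if (length(predicted) < 3) stop("need at least 3 subjects to correlate")
  if (stats::sd(observed) == 0) stop("observed scores are constant")
  r <- if (stats::sd(predicted) == 0) {
    warning("constant predictions; reporting r = 0")
    0
  } else {
    stats::cor(predicted, observed)
  }
  out <- list(r = r)
  if (!is.null(confounds)) {
    Z <- cbind(1, as.matrix(confounds))
    qz <- qr(Z)
    rp <- qr.resid(qz, predicted)
    ro <- qr.resid(qz, observed)
    out$partial_r <- if (sqrt(sum(rp^2)) == 0 || sqrt(sum(ro^2)) == 0) {
      warning("constant residualized vector; reporting partial r = 0")
      0
    } else {
      sum(rp * ro) / (sqrt(sum(rp^2)) * sqrt(sum(ro^2)))
    }
  }
  out
}

#' Leave-one-out cross-validated CPM
#'
#' For each left-out subject: edges are selected on the remaining n - 1
#' subjects ((partial) correlation with the target at strict
#' `p < threshold`), positive/negative network strengths are summed, a
#' normalized linear model is fit, and the left-out subject's score is
#' predicted with training-set normalization parameters. Folds whose mask
#' is empty predict the training mean (counted as degenerate).
#'
#' @param dataset A [cpm_dataset()].
#' @param config A [cpm_config()]; `config$confound_names` activates
#'   partial-correlation selection and partial-r evaluation.
#' @return An object of class `cpm_cv` with elements `positive` and
#'   `negative`, each containing `predicted`, `observed`, `fold_masks`,
#'   `fold_models`, `performance_r`, `performance_partial_r`,
#'   `n_degenerate`; plus `scheme` metadata.
#' @export
cpm_loocv <- function(dataset, config = cpm_config()) {
  n <- nrow(dataset$edge_matrix)
  run_cv_scheme(dataset, config, fold_id = seq_len(n), scheme = "loo")
}

#' Repeated k-fold cross-validated CPM
#'
#' Subjects are randomly partitioned into k folds (the first `n mod k`
#' folds receive one extra subject; assignment by seeded shuffle). The
#' CPM procedure of [cpm_loocv()] runs per fold; the performance r is
#' computed over all pooled out-of-fold predictions, the partition is
#' redrawn `kfold_repeats` times, and the final performance is the mean r
#' across repeats. Per-repeat r values are retained.
#'
#' @inheritParams cpm_loocv
#' @return A `cpm_cv` object; `positive`/`negative` carry `repeat_r`
#'   (per-repeat pooled r), `performance_r` (their mean), `predicted`
#'   (mean across repeats), and the first repeat's `fold_masks` and
#'   `fold_models`.
#' @export
cpm_kfold <- function(dataset, config = cpm_config(cv_scheme = "kfold")) {
  n <- nrow(dataset$edge_matrix)
  k <- config$k
  if (k > n) stop(sprintf("k = %d exceeds the sample size n = %d", k, n))
  parts <- with_seed(config$rng_seed,
                     lapply(seq_len(config$kfold_repeats), function(i) kfold_partition(n, k)))
  run_repeated_kfold(dataset, config, parts)
}

#' Permutation test for a cross-validated CPM model
#'
#' Rebuilds the null distribution of the performance statistic by
#' shuffling scores across subjects (edges and confounds stay attached to
#' their subjects) and rerunning the complete cross-validation pipeline,
#' selection included, for each permutation. With confounds, the
#' statistic is the partial r, recomputed per permutation. The p-value is
#' `(#{r_perm >= r_obs} + 1) / (m + 1)`; the raw proportion
#' `#{r_perm >= r_obs} / m` is also reported.
#'
#' @param dataset A `cpm_dataset`.
#' @param config A `cpm_config`; `n_permutations` must be >= 1. For the
#'   k-fold scheme each permutation uses `perm_kfold_repeats` repetitions.
#' @param cv The observed [cpm_loocv()]/[cpm_kfold()] result.
#' @param network `"positive"` or `"negative"`.
#' @return List with `p`, `p_raw`, `observed` (the observed statistic),
#'   `null_distribution` and `n_permutations`.
#' @export
permutation_test <- function(dataset, config, cv, network = c("negative", "positive")) {
  network <- match.arg(network)
  m <- config$n_permutations
  if (m < 1) stop("n_permutations must be >= 1")
  stopifnot(inherits(cv, "cpm_cv"))
  use_partial <- length(config$confound_names) > 0
  obs <- if (use_partial) cv[[network]]$performance_partial_r else cv[[network]]$performance_r
  n <- nrow(dataset$edge_matrix)

  xp <- prep_edge_stats(dataset$edge_matrix)
  loo_ctx <- if (config$cv_scheme == "loo") {
    make_cv_context(xp, dataset_z(dataset, config), seq_len(n),
                    config$selection_p_threshold)
  }
  null_r <- with_seed(config$rng_seed + 1L, {
    vapply(seq_len(m), function(b) {
      y_perm <- sample.int(n)
      ds <- dataset
      ds$behavior[[ds$target_name]] <- dataset_scores(dataset)[y_perm]
      res <- if (config$cv_scheme == "loo") {
        run_cv_scheme(ds, config, fold_id = seq_len(n), scheme = "loo",
                      store_masks = FALSE, quiet = TRUE, ctx = loo_ctx)
      } else {
        parts <- lapply(seq_len(config$perm_kfold_repeats),
                        function(i) kfold_partition(n, config$k))
        run_repeated_kfold(ds, config, parts, store_masks = FALSE, quiet = TRUE,
                           xp = xp)
      }
      if (use_partial) res[[network]]$performance_partial_r else res[[network]]$performance_r
    }, numeric(1))
  })

  b <- sum(null_r >= obs)
  list(p = (b + 1) / (m + 1), p_raw = b / m, observed = obs,
       null_distribution = null_r, n_permutations = m)
}

#' Full-sample edge weights for contributing-network characterization
#'
#' The (partial) correlation of every edge with the target computed on
#' the entire sample, used as the weights of contributing-network edges.
#'
#' @param dataset A `cpm_dataset`.
#' @return Numeric vector of per-edge correlations.
#' @export
full_sample_edge_weights <- function(dataset) {
  correlate_edges(dataset$edge_matrix, dataset_scores(dataset),
                  dataset_confounds(dataset))$r
}

#' @export
print.cpm_cv <- function(x, ...) {
  cat(sprintf("<cpm_cv> scheme %s, %d subjects\n", x$scheme$cv_scheme, length(x$negative$predicted)))
  for (side in c("positive", "negative")) {
    cat(sprintf("  %s network: r = %.4f%s, degenerate folds: %d\n", side,
                x[[side]]$performance_r,
                if (!is.null(x[[side]]$performance_partial_r)) {
                  sprintf(", partial r = %.4f", x[[side]]$performance_partial_r)
                } else "",
                x[[side]]$n_degenerate))
  }
  invisible(x)
}

## ------------------------------------------------------------------------
## internal cross-validation engine
##
## All folds of one partition are processed from shared sufficient
## statistics: per-fold training sums are global sums minus held-out group
## sums, which makes per-fold edge-score (partial) correlations O(nE)
## overall instead of O(n^2 E). Partial correlations come from the
## correlation-matrix Schur complement, algebraically identical to
## residualizing on the confounds.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

kfold_partition <- function(n, k) {
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold_id <- integer(n)
  fold_id[sample.int(n)] <- rep.int(seq_len(k), sizes)
  fold_id
}

# critical |r| equivalent to two-sided p < threshold at the given df
critical_r <- function(threshold, df) {
  t_crit <- stats::qt(1 - threshold / 2, df)
  t_crit / sqrt(df + t_crit^2)
}

# Reusable centered copies of the edge matrix (shared across partitions
# and across permutations, which only reshuffle y).
prep_edge_stats <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  list(X = X, Xc = Xc, cs_x = colSums(Xc), cs_xx = colSums(Xc * Xc))
}

# y-independent per-partition context: per-fold training variances of
# every edge, and the confound projections needed for partial
# correlations (Schur complement on the correlation matrix).
make_cv_context <- function(xp, Z, fold_id, threshold) {
  Xc <- xp$Xc
  n <- nrow(Xc); E <- ncol(Xc)
  F_ <- max(fold_id)
  fold_sizes <- tabulate(fold_id, nbins = F_)
  if (any(fold_sizes == 0)) stop("every fold must contain at least one subject")
  m <- n - fold_sizes
  C <- if (is.null(Z)) 0L else ncol(Z)
  if (any(m <= C + 3)) {
    stop("insufficient sample for selection (training n <= confounds + 3)")
  }
  # fast path only when fold f's test set is exactly subject f
  loo <- identical(as.integer(fold_id), seq_len(n))
  folds <- if (loo) as.list(seq_len(n)) else unname(split(seq_len(n), fold_id))

  X2 <- Xc * Xc
  if (loo) {
    ts_x <- Xc; ts_xx <- X2
  } else {
    ts_x <- rowsum(Xc, fold_id); ts_xx <- rowsum(X2, fold_id)
  }
  gs_x <- matrix(xp$cs_x, F_, E, byrow = TRUE) - ts_x
  var_x <- matrix(xp$cs_xx, F_, E, byrow = TRUE) - ts_xx - gs_x^2 / m
  zero_var <- var_x <= 1e-28
  var_x[zero_var] <- 1
  inv_sd_x <- 1 / sqrt(var_x)

  ctx <- list(n = n, E = E, F_ = F_, m = m, C = C, loo = loo,
              fold_id = fold_id, folds = folds,
              X = xp$X, Xc = Xc,
              gs_x = gs_x, inv_sd_x = inv_sd_x, zero_var = zero_var,
              r_crit = critical_r(threshold, m - 2 - C),
              Zc = NULL, zstats = NULL)
  if (C > 0) {
    Zc <- sweep(Z, 2, colMeans(Z))
    tot_ztz <- crossprod(Zc)
    tot_xtz <- crossprod(Xc, Zc)
    cs_z <- colSums(Zc)
    zstats <- vector("list", F_)
    for (f in seq_len(F_)) {
      test <- ctx$folds[[f]]
      Zt <- Zc[test, , drop = FALSE]
      gz <- cs_z - colSums(Zt)
      mz <- gz / m[f]
      cov_zz <- (tot_ztz - crossprod(Zt)) - outer(gz, mz)
      sd_z <- sqrt(pmax(diag(cov_zz), .Machine$double.xmin))
      Rzz_inv <- solve(cov_zz / outer(sd_z, sd_z))
      cov_xz <- (tot_xtz - crossprod(Xc[test, , drop = FALSE], Zt)) -
        outer(gs_x[f, ], mz)
      cor_xz <- cov_xz * outer(ctx$inv_sd_x[f, ], 1 / sd_z)
      cor_xz[zero_var[f, ], ] <- 0
      a <- cor_xz %*% Rzz_inv
      zstats[[f]] <- list(gs_z = gz, sd_z = sd_z, Rzz_inv = Rzz_inv,
                          a = a, t1 = rowSums(a * cor_xz))
    }
    ctx$Zc <- Zc
    ctx$zstats <- zstats
  }
  ctx
}

# Per-fold training (partial) correlations of every edge with y, as an
# F x E matrix, from group-subtracted sufficient statistics. Also returns
# the per-fold training mean/variance of y for reuse by the model fits.
foldwise_edge_correlations <- function(ctx, yc) {
  F_ <- ctx$F_; m <- ctx$m
  Xy <- ctx$Xc * yc
  if (ctx$loo) {
    ts_xy <- Xy; ts_y <- yc; ts_yy <- yc^2
  } else {
    ts_xy <- rowsum(Xy, ctx$fold_id)
    ts_y <- rowsum(yc, ctx$fold_id)[, 1]
    ts_yy <- rowsum(yc^2, ctx$fold_id)[, 1]
  }
  gs_xy <- matrix(colSums(Xy), F_, ctx$E, byrow = TRUE) - ts_xy
  gs_y <- sum(yc) - ts_y
  gs_yy <- sum(yc^2) - ts_yy
  var_y <- gs_yy - gs_y^2 / m
  inv_sd_y <- 1 / sqrt(var_y)

  r <- (gs_xy - ctx$gs_x * (gs_y / m)) * ctx$inv_sd_x * inv_sd_y
  r[ctx$zero_var] <- 0
  fold_y <- list(mean = gs_y / m, var = var_y / (m - 1))
  if (is.null(ctx$zstats)) return(list(r = r, fold_y = fold_y))

  Zy <- ctx$Zc * yc
  cs_zy <- colSums(Zy)
  for (f in seq_len(F_)) {
    zs <- ctx$zstats[[f]]
    test <- ctx$folds[[f]]
    gzy <- cs_zy - if (length(test) == 1) Zy[test, ] else colSums(Zy[test, , drop = FALSE])
    cov_zy <- gzy - zs$gs_z * gs_y[f] / m[f]
    cor_zy <- cov_zy / zs$sd_z * inv_sd_y[f]
    t2 <- drop(zs$a %*% cor_zy)
    t3 <- drop(crossprod(cor_zy, zs$Rzz_inv %*% cor_zy))
    den <- (1 - zs$t1) * (1 - t3)
    bad <- den <= 0 | ctx$zero_var[f, ]
    den[bad] <- 1
    rf <- (r[f, ] - t2) / sqrt(den)
    rf[bad] <- 0
    r[f, ] <- rf
  }
  list(r = r, fold_y = fold_y)
}

# One partition of the CPM procedure over both network signs.
cpm_cv_engine <- function(ctx, y, normalize_edges = FALSE,
                          store_masks = TRUE, store_models = TRUE) {
  n <- ctx$n; E <- ctx$E
  F_ <- ctx$F_
  X <- ctx$X
  if (stats::sd(y) == 0) stop("scores are constant; correlation undefined")

  y_bar <- mean(y)
  res <- foldwise_edge_correlations(ctx, y - y_bar)
  r_fold <- res$r
  fold_y_mean <- res$fold_y$mean + y_bar
  fold_y_sd <- sqrt(res$fold_y$var)
  r_crit <- ctx$r_crit
  total_y <- sum(y)

  pred <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("positive", "negative")))
  masks <- if (store_masks) list(positive = vector("list", F_), negative = vector("list", F_))
  models <- if (store_models) {
    list(positive = matrix(NA_real_, F_, 6), negative = matrix(NA_real_, F_, 6))
  }
  model_cols <- c("slope", "intercept", "strength_mean", "strength_sd",
                  "score_mean", "score_sd")
  n_degen <- c(positive = 0L, negative = 0L)

  for (f in seq_len(F_)) {
    test <- ctx$folds[[f]]
    rf <- r_fold[f, ]
    mf <- ctx$m[f]
    y_mean <- fold_y_mean[f]; y_sd <- fold_y_sd[f]
    sum_y_tr <- total_y - sum(y[test])
    for (side in c("positive", "negative")) {
      sel <- if (side == "positive") which(rf > r_crit[f]) else which(rf < -r_crit[f])
      if (store_masks) {
        mk <- logical(E); mk[sel] <- TRUE
        masks[[side]][[f]] <- mk
      }
      degen <- TRUE
      s_mean <- 0; s_sd <- 1; slope <- 0; intercept <- 0
      if (length(sel) > 0) {
        if (normalize_edges) {
          # z-score each selected edge with training parameters before summing
          train <- seq_len(n)[-test]
          sub <- X[, sel, drop = FALSE]
          mu <- colMeans(sub[train, , drop = FALSE])
          sdv <- apply(sub[train, , drop = FALSE], 2, stats::sd)
          sdv[sdv == 0] <- 1
          s_all <- rowSums(sweep(sweep(sub, 2, mu), 2, sdv, "/"))
        } else {
          s_all <- .rowSums(X[, sel, drop = FALSE], n, length(sel))
        }
        s_all <- s_all - sum(s_all) / n   # shift-invariant; improves conditioning
        st <- s_all[test]
        sum_s <- sum(s_all) - sum(st)
        sum_ss <- sum(s_all * s_all) - sum(st * st)
        s_mean <- sum_s / mf
        var_s <- (sum_ss - sum_s * s_mean) / (mf - 1)
        if (var_s > 0) {
          degen <- FALSE
          s_sd <- sqrt(var_s)
          sy <- s_all * y
          cov_sy <- ((sum(sy) - sum(sy[test])) - sum_s * sum_y_tr / mf) / (mf - 1)
          slope <- cov_sy / (s_sd * y_sd)  # OLS slope in normalized space; intercept 0
          pred[test, side] <- y_mean + slope * (st - s_mean) / s_sd * y_sd
        }
      }
      if (degen) {
        s_sd <- 1
        pred[test, side] <- y_mean
        n_degen[side] <- n_degen[side] + 1L
      }
      if (store_models) {
        models[[side]][f, ] <- c(slope, intercept, s_mean, s_sd, y_mean, y_sd)
      }
    }
  }
  if (store_models) {
    colnames(models$positive) <- model_cols
    colnames(models$negative) <- model_cols
  }
  list(predicted = pred, masks = masks, models = models, n_degenerate = n_degen)
}

cv_side_result <- function(side, eng, y, Z, quiet) {
  perf <- withCallingHandlers(
    evaluate_predictions(eng$predicted[, side], y, Z),
    warning = function(w) if (quiet) invokeRestart("muffleWarning")
  )
  list(predicted = eng$predicted[, side],
       observed = y,
       fold_masks = if (!is.null(eng$masks)) eng$masks[[side]],
       fold_models = if (!is.null(eng$models)) eng$models[[side]],
       performance_r = perf$r,
       performance_partial_r = perf$partial_r,
       n_degenerate = unname(eng$n_degenerate[side]))
}

dataset_z <- function(dataset, config) {
  if (length(config$confound_names) > 0) {
    as.matrix(dataset$behavior[config$confound_names])
  } else NULL
}

run_cv_scheme <- function(dataset, config, fold_id, scheme,
                          store_masks = TRUE, quiet = FALSE, ctx = NULL) {
  y <- dataset_scores(dataset)
  Z <- dataset_z(dataset, config)
  if (is.null(ctx)) {
    ctx <- make_cv_context(prep_edge_stats(dataset$edge_matrix), Z, fold_id,
                           config$selection_p_threshold)
  }
  eng <- cpm_cv_engine(ctx, y, normalize_edges = config$normalize_edges,
                       store_masks = store_masks, store_models = store_masks)
  structure(list(
    positive = cv_side_result("positive", eng, y, Z, quiet),
    negative = cv_side_result("negative", eng, y, Z, quiet),
    scheme = list(cv_scheme = scheme, k = if (scheme == "kfold") config$k,
                  repeats = if (scheme == "kfold") config$kfold_repeats,
                  seed = config$rng_seed)
  ), class = "cpm_cv")
}

run_repeated_kfold <- function(dataset, config, partitions,
                               store_masks = TRUE, quiet = FALSE, xp = NULL) {
  y <- dataset_scores(dataset)
  Z <- dataset_z(dataset, config)
  if (is.null(xp)) xp <- prep_edge_stats(dataset$edge_matrix)
  R <- length(partitions)
  acc_pred <- list(positive = 0, negative = 0)
  rep_r <- list(positive = numeric(R), negative = numeric(R))
  rep_pr <- list(positive = numeric(R), negative = numeric(R))
  first <- NULL
  for (i in seq_len(R)) {
    keep <- store_masks && i == 1L
    ctx <- make_cv_context(xp, Z, partitions[[i]], config$selection_p_threshold)
    eng <- cpm_cv_engine(ctx, y, normalize_edges = config$normalize_edges,
                         store_masks = keep, store_models = keep)
    if (keep) first <- eng
    for (side in c("positive", "negative")) {
      perf <- withCallingHandlers(
        evaluate_predictions(eng$predicted[, side], y, Z),
        warning = function(w) if (quiet) invokeRestart("muffleWarning")
      )
      rep_r[[side]][i] <- perf$r
      if (!is.null(perf$partial_r)) rep_pr[[side]][i] <- perf$partial_r
      acc_pred[[side]] <- acc_pred[[side]] + eng$predicted[, side]
    }
  }
  side_result <- function(side) {
    list(predicted = acc_pred[[side]] / R,
         observed = y,
         fold_masks = if (!is.null(first)) first$masks[[side]],
         fold_models = if (!is.null(first)) first$models[[side]],
         repeat_r = rep_r[[side]],
         performance_r = mean(rep_r[[side]]),
         performance_partial_r = if (is.null(Z)) NULL else mean(rep_pr[[side]]),
         n_degenerate = if (!is.null(first)) unname(first$n_degenerate[side]) else NA_integer_)
  }
  structure(list(
    positive = side_result("positive"),
    negative = side_result("negative"),
    scheme = list(cv_scheme = "kfold", k = config$k, repeats = R,
                  seed = config$rng_seed)
  ), class = "cpm_cv")
}
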