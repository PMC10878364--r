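# Brute-force CPM reference: explicit per-fold loops and textbook
# formulas (cor.test, lm, residuals), independent of the package's
# incremental sufficient-statistic engine.

oracle_edge_cor <- function(X, y, Z = NULL) {
  E <- ncol(X)
  r <- numeric(E); p <- numeric(E)
  if (!is.null(Z)) {
    fit_y <- stats::lm.fit(cbind(1, Z), y)
    ry <- fit_y$residuals
  }
  for (e in seq_len(E)) {
    x <- X[, e]
    if (stats::sd(x) == 0) { r[e] <- 0; p[e] <- 1; next }
    if (is.null(Z)) {
      ct <- stats::cor.test(x, y)
      r[e] <- unname(ct$estimate)
      p[e] <- ct$p.value
    } else {
      rx <- stats::lm.fit(cbind(1, Z), x)$residuals
      rr <- stats::cor(rx, ry)
      df <- length(y) - 2 - ncol(Z)
      tt <- rr * sqrt(df / (1 - rr^2))
      r[e] <- rr
      p[e] <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    }
  }
  list(r = r, p = p)
}

# One CV fold trained by explicit formulas; returns predictions for the
# test subjects and the per-sign masks/models.
oracle_fold <- function(X, y, Z, train, test, threshold) {
  sel <- oracle_edge_cor(X[train, , drop = FALSE], y[train],
                         if (is.null(Z)) NULL else Z[train, , drop = FALSE])
  out <- list()
  for (side in c("positive", "negative")) {
    mask <- if (side == "positive") {
      sel$p < threshold & sel$r > 0
    } else {
      sel$p < threshold & sel$r < 0
    }
    s_all <- rowSums(X[, mask, drop = FALSE])
    s_tr <- s_all[train]; y_tr <- y[train]
    y_mean <- mean(y_tr); y_sd <- stats::sd(y_tr)
    if (sum(mask) == 0 || stats::sd(s_tr) == 0) {
      pred <- rep(y_mean, length(test))
      model <- c(slope = 0, intercept = 0, strength_mean = 0, strength_sd = 1,
                 score_mean = y_mean, score_sd = y_sd)
    } else {
      s_mean <- mean(s_tr); s_sd <- stats::sd(s_tr)
      zs <- (s_tr - s_mean) / s_sd
      zy <- (y_tr - y_mean) / y_sd
      fit <- stats::lm(zy ~ zs)
      b <- unname(stats::coef(fit))
      zt <- (s_all[test] - s_mean) / s_sd
      pred <- (b[1] + b[2] * zt) * y_sd + y_mean
      model <- c(slope = b[2], intercept = b[1], strength_mean = s_mean,
                 strength_sd = s_sd, score_mean = y_mean, score_sd = y_sd)
    }
    out[[side]] <- list(mask = mask, pred = pred, model = model)
  }
  out
}

oracle_loocv <- function(X, y, Z = NULL, threshold = 0.01) {
  n <- nrow(X)
  pred <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("positive", "negative")))
  masks <- list(positive = vector("list", n), negative = vector("list", n))
  for (i in seq_len(n)) {
    fo <- oracle_fold(X, y, Z, train = setdiff(seq_len(n), i), test = i, threshold)
    for (side in c("positive", "negative")) {
      pred[i, side] <- fo[[side]]$pred
      masks[[side]][[i]] <- fo[[side]]$mask
    }
  }
  perf <- lapply(c(positive = "positive", negative = "negative"), function(side) {
    r <- if (stats::sd(pred[, side]) == 0) 0 else stats::cor(pred[, side], y)
    pr <- NULL
    if (!is.null(Z)) {
      rp <- stats::lm.fit(cbind(1, Z), pred[, side])$residuals
      ro <- stats::lm.fit(cbind(1, Z), y)$residuals
      pr <- if (stats::sd(rp) == 0) 0 else stats::cor(rp, ro)
    }
    list(r = r, partial_r = pr)
  })
  list(pred = pred, masks = masks, perf = perf)
}

# Permutation test around oracle_loocv using the same permutation stream
# the package draws (sample.int(n) under seed+1).
oracle_permutation <- function(X, y, Z, threshold, obs, m, seed, network) {
  null_r <- withr::with_seed(seed + 1L, {
    vapply(seq_len(m), function(b) {
      yp <- y[sample.int(length(y))]
      res <- oracle_loocv(X, yp, Z, threshold)
      if (is.null(Z)) res$perf[[network]]$r else res$perf[[network]]$partial_r
    }, numeric(1))
  })
  b <- sum(null_r >= obs)
  list(p = (b + 1) / (m + 1), p_raw = b / m, null = null_r)
}
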