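test_that("correlate_edges matches textbook Pearson and partial correlation", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  out <- correlate_edges(matrix(x), y)
  expect_equal(out$r, cor(x, y), tolerance = 1e-12)
  expect_equal(out$r, 0.8220, tolerance = 1e-4)
  expect_equal(out$p, cor.test(x, y)$p.value, tolerance = 1e-12)

  # edge identical to the score: r = 1, p below any threshold
  out1 <- correlate_edges(matrix(y), y)
  expect_equal(out1$r, 1)
  expect_lt(out1$p, 1e-12)

  # a confound orthogonal to both edge and score leaves r unchanged
  withr::with_seed(31, {
    n <- 40
    e <- rnorm(n); s <- rnorm(n)
    z0 <- rnorm(n)
    z <- residuals(lm(z0 ~ e + s))       # exactly uncorrelated with both
  })
  plain <- correlate_edges(matrix(e), s)
  part <- correlate_edges(matrix(e), s, matrix(z))
  expect_equal(part$r, plain$r, tolerance = 1e-10)

  # partial correlation equals correlation of residuals (oracle route)
  withr::with_seed(32, {
    X <- matrix(rnorm(40 * 6), 40)
    s <- rnorm(40)
    Z <- cbind(rnorm(40), rbinom(40, 1, .5))
  })
  got <- correlate_edges(X, s, Z)
  want <- oracle_edge_cor(X, s, Z)
  expect_equal(got$r, want$r, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)

  # zero-variance edge: r = 0, p = 1
  Xz <- cbind(X[, 1], 5)
  gz <- correlate_edges(Xz, s)
  expect_equal(gz$r[2], 0)
  expect_equal(gz$p[2], 1)
  expect_equal(attr(gz, "n_zero_variance"), 1L)

  expect_error(correlate_edges(X, rep(1, 40)), "constant")
  expect_error(correlate_edges(X[1:4, ], s[1:4], Z[1:4, ]), "insufficient sample")
})

test_that("select_edges uses a strict threshold and splits by sign", {
  sel <- select_edges(c(0.5, -0.5, 0.4, 0), c(0.001, 0.001, 0.01, 0.0001), 0.01)
  expect_equal(sel$pos_mask, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(sel$neg_mask, c(FALSE, TRUE, FALSE, FALSE))  # p == threshold excluded; r == 0 never selected
  expect_length(intersect(which(sel$pos_mask), which(sel$neg_mask)), 0)
  all_null <- select_edges(c(0.2, -0.2), c(1, 1), 0.01)
  expect_false(any(all_null$pos_mask | all_null$neg_mask))
})

test_that("network_strength sums masked edges, empty mask gives zero", {
  expect_equal(network_strength(c(.5, .25, -.1), c(TRUE, TRUE, FALSE)), 0.75)
  expect_equal(network_strength(c(.5, .25, -.1), c(FALSE, FALSE, FALSE)), 0)
  expect_equal(network_strength(c(.1, .2, -.3), c(TRUE, TRUE, TRUE)), 0, tolerance = 1e-12)
  M <- rbind(c(1, 2, 3), c(4, 5, 6))
  expect_equal(network_strength(M, c(TRUE, FALSE, TRUE)), c(4, 10))
})

test_that("strength model normalizes with training parameters", {
  withr::with_seed(41, y <- rnorm(20, 100, 15))
  m <- fit_strength_model(y, y)
  expect_equal(m$slope, 1, tolerance = 1e-12)
  expect_equal(m$intercept, 0, tolerance = 1e-12)
  m2 <- fit_strength_model(-y, y)
  expect_equal(m2$slope, -1, tolerance = 1e-12)

  # training normalization invariant: z-scored strengths have mean 0, sd 1
  zs <- (y - m$strength_mean) / m$strength_sd
  expect_equal(mean(zs), 0, tolerance = 1e-10)
  expect_equal(sd(zs), 1, tolerance = 1e-10)

  # prediction at the training mean lands at score mean + intercept*sd
  expect_equal(predict_score(m, m$strength_mean),
               m$score_mean + m$intercept * m$score_sd)
  # identity model one training sd above the mean: one score sd above the mean
  expect_equal(predict_score(m, m$strength_mean + m$strength_sd),
               m$score_mean + m$score_sd, tolerance = 1e-10)

  expect_warning(md <- fit_strength_model(rep(2, 10), y[1:10]), "degenerate")
  expect_true(md$degenerate)
  expect_equal(predict_score(md, 123), mean(y[1:10]))
  expect_error(fit_strength_model(y, rep(1, 20)), "constant")
})

test_that("evaluate_predictions returns r and residualized partial r", {
  withr::with_seed(51, {
    obs <- rnorm(30)
    Z <- cbind(rnorm(30))
    pred <- obs + rnorm(30, sd = 0.5)
  })
  expect_equal(evaluate_predictions(obs, obs)$r, 1)
  expect_equal(evaluate_predictions(-obs, obs)$r, -1)
  # oracle: partial r is the correlation of lm residuals
  ev <- evaluate_predictions(pred, obs, Z)
  expect_equal(ev$partial_r,
               cor(residuals(lm(pred ~ Z)), residuals(lm(obs ~ Z))),
               tolerance = 1e-10)
  z_orth <- residuals(lm(Z[, 1] ~ obs))
  ev2 <- evaluate_predictions(obs, obs, cbind(z_orth))
  expect_equal(ev2$partial_r, 1, tolerance = 1e-10)
  expect_warning(ev3 <- evaluate_predictions(rep(1, 30), obs), "constant predictions")
  expect_equal(ev3$r, 0)
})

test_that("noiseless planted edge gives near-perfect LOOCV prediction", {
  sd1 <- generate_dataset(noiseless_spec(seed = 5))
  cv <- cpm_loocv(sd1$dataset, cpm_config(n_permutations = 0))
  expect_gt(cv$negative$performance_r, 0.99)
  expect_equal(cv$negative$n_degenerate, 0)
  # the planted edge is in every fold's negative mask
  pos <- sd1$truth$signal_edges$edge_pos
  expect_true(all(vapply(cv$negative$fold_masks, function(m) m[pos], logical(1))))
})

test_that("LOOCV is invariant to subject order and to duplicating subjects", {
  sd1 <- generate_dataset(synthetic_spec(n_subjects = 24, n_nodes = 10, seed = 14,
                                         signal_edges = data.frame(i = 0, j = 1, beta = -0.9)))
  ds <- sd1$dataset
  cfg <- cpm_config(n_permutations = 0)
  cv <- cpm_loocv(ds, cfg)

  perm <- withr::with_seed(1, sample(nrow(ds$edge_matrix)))
  ds2 <- ds
  ds2$edge_matrix <- ds$edge_matrix[perm, ]
  ds2$behavior <- ds$behavior[perm, ]
  cv2 <- cpm_loocv(ds2, cfg)
  expect_equal(cv2$negative$predicted, cv$negative$predicted[perm], tolerance = 1e-10)
  expect_equal(cv2$negative$performance_r, cv$negative$performance_r, tolerance = 1e-10)

  # duplicated subjects: the two copies of a left-out pattern share masks
  ds3 <- ds
  ds3$edge_matrix <- rbind(ds$edge_matrix, ds$edge_matrix)
  beh <- rbind(ds$behavior, transform(ds$behavior, subject_id = paste0(subject_id, "b")))
  ds3$behavior <- beh
  cv3 <- cpm_loocv(ds3, cfg)
  n <- nrow(ds$edge_matrix)
  for (i in c(1, 7, n)) {
    expect_identical(cv3$negative$fold_masks[[i]], cv3$negative$fold_masks[[i + n]])
  }
})

test_that("k-fold with k = n reproduces LOOCV exactly", {
  sd1 <- generate_dataset(synthetic_spec(n_subjects = 20, n_nodes = 8, seed = 33,
                                         signal_edges = data.frame(i = 0, j = 1, beta = -0.7)))
  cfg_loo <- cpm_config(n_permutations = 0)
  cfg_kn <- cpm_config(cv_scheme = "kfold", k = 20, kfold_repeats = 1,
                       n_permutations = 0, rng_seed = 77)
  cv_loo <- cpm_loocv(sd1$dataset, cfg_loo)
  cv_kn <- cpm_kfold(sd1$dataset, cfg_kn)
  expect_equal(cv_kn$negative$predicted, cv_loo$negative$predicted)
  expect_equal(cv_kn$positive$predicted, cv_loo$positive$predicted)
  expect_equal(cv_kn$negative$performance_r, cv_loo$negative$performance_r)
})

test_that("repeated k-fold is deterministic and averages per-repeat r", {
  sd1 <- generate_dataset(synthetic_spec(n_subjects = 40, n_nodes = 10, seed = 6,
                                         signal_edges = data.frame(i = 0, j = 1, beta = -0.8)))
  cfg <- cpm_config(cv_scheme = "kfold", k = 5, kfold_repeats = 8,
                    n_permutations = 0, rng_seed = 9)
  cv1 <- cpm_kfold(sd1$dataset, cfg)
  cv2 <- cpm_kfold(sd1$dataset, cfg)
  expect_identical(cv1$negative$performance_r, cv2$negative$performance_r)
  expect_length(cv1$negative$repeat_r, 8)
  expect_equal(cv1$negative$performance_r, mean(cv1$negative$repeat_r))
  expect_gt(cv1$negative$performance_r, 0.5)
  expect_error(cpm_kfold(sd1$dataset, cpm_config(cv_scheme = "kfold", k = 41)),
               "exceeds the sample size")
})

test_that("positive and negative masks are disjoint and cover all selected edges", {
  ds <- tiny_dataset(30, 8, seed = 61)
  cv <- cpm_loocv(ds, cpm_config(selection_p_threshold = 0.2, n_permutations = 0))
  sel <- correlate_edges(ds$edge_matrix, dataset_scores(ds))
  es <- select_edges(sel$r, sel$p, 0.2)
  expect_equal(sum(es$pos_mask & es$neg_mask), 0)
  expect_equal(sum(es$pos_mask | es$neg_mask), sum(sel$p < 0.2 & sel$r != 0))
  for (f in c(1, 15, 30)) {
    expect_equal(sum(cv$positive$fold_masks[[f]] & cv$negative$fold_masks[[f]]), 0)
  }
})

test_that("permutation test is deterministic, bounded and exact in the noiseless limit", {
  sd1 <- generate_dataset(noiseless_spec(seed = 16))
  cfg0 <- cpm_config(n_permutations = 0)
  cv <- cpm_loocv(sd1$dataset, cfg0)
  cfg <- cpm_config(n_permutations = 99, rng_seed = 4)
  pt1 <- permutation_test(sd1$dataset, cfg, cv, "negative")
  pt2 <- permutation_test(sd1$dataset, cfg, cv, "negative")
  expect_identical(pt1$p, pt2$p)
  expect_identical(pt1$null_distribution, pt2$null_distribution)
  # no permutation can match a perfect r: p = 1/(m+1)
  expect_equal(pt1$p, 1 / 100)
  expect_equal(pt1$p_raw, 0)
  # observed below every permuted value gives p = 1
  fake <- cv
  fake$negative$performance_r <- -2
  ptl <- permutation_test(sd1$dataset, cfg, fake, "negative")
  expect_equal(ptl$p, 1)
  expect_error(permutation_test(sd1$dataset, cfg0, cv, "negative"), ">= 1")
})
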