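test_that("generation is deterministic given the seed", {
  spec <- synthetic_spec(n_subjects = 20, n_nodes = 8, seed = 7, missing_rate = 0.1)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a$dataset$edge_matrix, b$dataset$edge_matrix)
  expect_identical(a$dataset$behavior, b$dataset$behavior)
  expect_identical(a$panel, b$panel)
  c_ <- generate_dataset(synthetic_spec(n_subjects = 20, n_nodes = 8, seed = 8,
                                        missing_rate = 0.1))
  expect_false(identical(a$dataset$edge_matrix, c_$dataset$edge_matrix))
})

test_that("noiseless planted edge correlates perfectly with the score", {
  sd1 <- generate_dataset(noiseless_spec(seed = 2))
  pos <- sd1$truth$signal_edges$edge_pos
  r <- cor(sd1$dataset$edge_matrix[, pos], dataset_scores(sd1$dataset))
  expect_equal(r, -1, tolerance = 1e-12)
})

test_that("planted-edge correlation converges to beta/sqrt(beta^2+sigma^2)", {
  beta <- -0.35; sigma <- 1
  # a single n=5000 draw has Monte Carlo sd ~ 0.013 on r, so average a few
  r <- vapply(1:5, function(s) {
    sd1 <- generate_dataset(synthetic_spec(n_subjects = 5000, n_nodes = 6,
                                           noise_sd = sigma,
                                           signal_edges = data.frame(i = 0, j = 1,
                                                                     beta = beta),
                                           seed = s))
    cor(sd1$dataset$edge_matrix[, sd1$truth$signal_edges$edge_pos],
        dataset_scores(sd1$dataset))
  }, numeric(1))
  expect_lt(abs(mean(r) - beta / sqrt(beta^2 + sigma^2)), 0.02)
})

test_that("null spec produces edges unrelated to the score", {
  # no fixed edge reaches p < 0.001 in more than half of seeded replicates
  hits <- integer(n_edges(8))
  for (s in 1:20) {
    nd <- generate_dataset(null_spec(n_subjects = 60, n_nodes = 8, seed = s))
    ce <- correlate_edges(nd$dataset$edge_matrix, dataset_scores(nd$dataset))
    hits <- hits + (ce$p < 0.001)
  }
  expect_true(all(hits <= 10))
})

test_that("spec validation rejects infeasible parameters", {
  expect_error(synthetic_spec(fd_exceed_fraction = 1.5), "fd_exceed_fraction")
  expect_error(synthetic_spec(missing_rate = 1), "missing_rate")
  expect_error(synthetic_spec(n_nodes = 10,
                              signal_edges = data.frame(i = 3, j = 3, beta = 1)),
               "upper triangle")
  expect_error(synthetic_spec(n_nodes = 10,
                              signal_edges = data.frame(i = 0, j = 10, beta = 1)),
               "upper triangle")
})

test_that("mean FD exceeds 0.3 at roughly the configured rate and panel has holes", {
  spec <- synthetic_spec(n_subjects = 2000, n_nodes = 4, fd_exceed_fraction = 0.1,
                         missing_rate = 0.15, seed = 23,
                         signal_edges = data.frame(i = integer(0), j = integer(0),
                                                   beta = numeric(0)))
  sd1 <- generate_dataset(spec)
  frac <- mean(sd1$dataset$behavior$mean_fd > 0.3)
  expect_gt(frac, 0.07); expect_lt(frac, 0.13)
  miss <- mean(is.na(as.matrix(sd1$panel)))
  expect_gt(miss, 0.12); expect_lt(miss, 0.18)
  expect_true(all(sd1$dataset$behavior$mean_fd >= 0))
  # filtering then drops about that fraction
  kept <- filter_by_motion(sd1$dataset$behavior)$retained
  expect_equal(nrow(kept), sum(sd1$dataset$behavior$mean_fd <= 0.3))
})

test_that("confound leakage induces the requested associations", {
  spec <- synthetic_spec(n_subjects = 800, n_nodes = 8, seed = 37,
                         signal_edges = data.frame(i = 0, j = 1, beta = -0.5),
                         confound_score_loadings = c(age = 0.4),
                         confound_edge_loadings = c(age = 0.3))
  sd1 <- generate_dataset(spec)
  beh <- sd1$dataset$behavior
  expect_gt(cor(beh$age, beh$score), 0.25)
  pos <- sd1$truth$signal_edges$edge_pos
  expect_gt(cor(beh$age, sd1$dataset$edge_matrix[, pos]), 0.1)
})

test_that("simulated time series converge to the target correlation structure", {
  # identity target: all sample correlations stay small at large T
  id_fc <- fc_matrix(matrix(0, 5, 5))
  ts <- generate_timeseries(id_fc, 5000, seed = 3)
  r <- cor(ts)
  expect_true(all(abs(r[upper.tri(r)]) < 0.1))

  # a planted pair at r = 0.5 is recovered within sampling error
  z <- matrix(0, 4, 4)
  z[1, 2] <- z[2, 1] <- atanh(0.5)
  ts2 <- generate_timeseries(fc_matrix(z), 10000, seed = 5)
  expect_equal(cor(ts2)[1, 2], 0.5, tolerance = 0.05)
  # and feeding it back through the FC stage reproduces the edge
  fc <- timeseries_to_fc(ts2)
  expect_equal(fc[1, 2], atanh(0.5), tolerance = 0.1)

  expect_error(generate_timeseries(id_fc, 2), "3 timepoints")
  bad <- matrix(atanh(0.99), 3, 3); diag(bad) <- 0
  bad[1, 2] <- bad[2, 1] <- -atanh(0.99)
  expect_error(generate_timeseries(fc_matrix(bad), 100), "positive definite")
})

test_that("on-disk synthetic layout feeds straight back into the pipeline", {
  dir <- withr::local_tempdir()
  sd1 <- generate_dataset(synthetic_spec(n_subjects = 8, n_nodes = 6, seed = 11,
                                         missing_rate = 0.1,
                                         signal_edges = data.frame(i = 0, j = 1,
                                                                   beta = -0.6)))
  write_synthetic_dataset(sd1, dir)
  expect_length(list.files(file.path(dir, "fc")), 8)
  beh <- read_behavior_table(file.path(dir, "behavior.tsv"), "score",
                             c("age", "sex", "mean_fd", "negative_emotion"))
  mats <- lapply(beh$subject_id, function(id) {
    read_connectivity_matrix(file.path(dir, "fc", paste0(id, ".tsv")), 6)
  })
  names(mats) <- beh$subject_id
  ds <- assemble_dataset(mats, beh, "score",
                         c("age", "sex", "mean_fd", "negative_emotion"))
  expect_equal(ds$edge_matrix, sd1$dataset$edge_matrix, tolerance = 1e-12,
               ignore_attr = TRUE)
  atlas <- read_atlas(file.path(dir, "atlas.tsv"))
  expect_equal(nrow(atlas), 6)
})
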