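# Small in-code fixtures shared across test files.

random_symmetric_fc <- function(n_nodes, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_nodes^2), n_nodes)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    fc_matrix(m)
  })
}

# A tiny random cpm_dataset (optionally with confounds) for engine tests.
tiny_dataset <- function(n, n_nodes, seed = 1, with_confounds = FALSE) {
  E <- n_edges(n_nodes)
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * E), n, E)
    beh <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                      score = rnorm(n, 100, 20))
    conf <- character()
    if (with_confounds) {
      beh$age <- rnorm(n, 20, 3)
      beh$sex <- rbinom(n, 1, 0.5)
      conf <- c("age", "sex")
    }
    cpm_dataset(X, beh, n_nodes, "score", conf)
  })
}

null_spec <- function(n_subjects = 100, n_nodes = 30, seed = 1) {
  synthetic_spec(n_subjects = n_subjects, n_nodes = n_nodes,
                 signal_edges = data.frame(i = integer(0), j = integer(0),
                                           beta = numeric(0)),
                 seed = seed)
}

noiseless_spec <- function(n_subjects = 30, n_nodes = 10, seed = 1) {
  synthetic_spec(n_subjects = n_subjects, n_nodes = n_nodes, noise_sd = 0,
                 signal_edges = data.frame(i = 0, j = 1, beta = -1),
                 seed = seed)
}
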