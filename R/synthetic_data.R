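#' Specification for a synthetic connectome-behavior dataset
#'
#' Describes the generating model for datasets with the statistical
#' structure the CPM analysis assumes, with known ground truth: a
#' continuous behavioral score, a small designated set of signal edges
#' loaded on the (standardized) score, pure-noise background edges on the
#' Fisher-z scale, confounds (age, sex, mean FD, a one-factor
#' negative-emotion panel) with configurable leakage, and configurable
#' behavioral missingness.
#'
#' Defaults encode the study conditions the package's validation suite
#' assumes: 300 subjects, 60 nodes, 12 negative signal edges with
#' beta = -0.35, unit edge noise, and a questionnaire-like score
#' (mean 101.07, sd 20.41). `n_nodes = 268` with n = 677 is the
#' paper-scale preset ([synthetic_spec_paper_scale()]).
#'
#' @param n_subjects Number of subjects (default 300).
#' @param n_nodes Number of nodes (default 60; 268 supported).
#' @param signal_edges data.frame with 0-based columns `i`, `j` (i < j)
#'   and `beta`; default 12 disjoint node pairs with beta = -0.35.
#' @param noise_sd Residual sd of edge values on the Fisher-z scale
#'   (default 1).
#' @param score_mean,score_sd Score distribution (defaults 101.07, 20.41).
#' @param confound_score_loadings Named numeric vector: loading of each
#'   standardized confound onto the standardized score (default all 0).
#' @param confound_edge_loadings Named numeric vector: additive loading of
#'   each standardized confound onto every signal edge (default all 0).
#' @param emotion_score_cor Correlation between the latent negative-
#'   emotion factor and the score (default 0.3).
#' @param emotion_loadings True one-factor loadings of the five subscales
#'   (defaults 0.78, 0.636, 0.786, 0.818, 0.756).
#' @param fd_mean,fd_sd Mean-FD distribution below the exclusion point
#'   (defaults 0.15, 0.06 mm).
#' @param fd_exceed_fraction Expected fraction of subjects with mean FD
#'   above 0.3 (default 0.02).
#' @param missing_rate Fraction of emotion-panel cells masked as missing
#'   (default 0).
#' @param seed Integer seed (default 1).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 300L,
                           n_nodes = 60L,
                           signal_edges = default_signal_edges(n_nodes),
                           noise_sd = 1,
                           score_mean = 101.07,
                           score_sd = 20.41,
                           confound_score_loadings = c(age = 0, sex = 0, mean_fd = 0,
                                                       negative_emotion = 0),
                           confound_edge_loadings = c(age = 0, sex = 0, mean_fd = 0,
                                                      negative_emotion = 0),
                           emotion_score_cor = 0.3,
                           emotion_loadings = c(state_anxiety = 0.78, depression = 0.636,
                                                perceived_stress = 0.786,
                                                negative_affect = 0.818,
                                                loneliness = 0.756),
                           fd_mean = 0.15, fd_sd = 0.06,
                           fd_exceed_fraction = 0.02,
                           missing_rate = 0,
                           seed = 1L) {
  stopifnot(n_subjects >= 2, n_nodes >= 2, noise_sd >= 0, score_sd > 0,
            abs(emotion_score_cor) <= 1, fd_sd >= 0)
  if (fd_exceed_fraction < 0 || fd_exceed_fraction > 1) {
    stop("fd_exceed_fraction must lie in [0, 1]")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  conf_names <- c("age", "sex", "mean_fd", "negative_emotion")
  fill <- function(v) {
    out <- stats::setNames(rep(0, length(conf_names)), conf_names)
    out[intersect(names(v), conf_names)] <- v[intersect(names(v), conf_names)]
    out
  }
  confound_score_loadings <- fill(confound_score_loadings)
  confound_edge_loadings <- fill(confound_edge_loadings)
  signal_edges <- as.data.frame(signal_edges)
  if (nrow(signal_edges) > 0) {
    stopifnot(all(c("i", "j", "beta") %in% names(signal_edges)))
    if (any(signal_edges$i >= signal_edges$j) || any(signal_edges$i < 0) ||
        any(signal_edges$j >= n_nodes)) {
      stop("signal edges must lie in the strict upper triangle (0 <= i < j < n_nodes)")
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
    signal_edges = signal_edges, noise_sd = noise_sd,
    score_mean = score_mean, score_sd = score_sd,
    confound_score_loadings = confound_score_loadings,
    confound_edge_loadings = confound_edge_loadings,
    emotion_score_cor = emotion_score_cor,
    emotion_loadings = emotion_loadings,
    fd_mean = fd_mean, fd_sd = fd_sd,
    fd_exceed_fraction = fd_exceed_fraction,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Default planted signal-edge set
#'
#' Twelve negative signal edges on disjoint node pairs
#' (0,1), (2,3), ..., (22,23) with beta = -0.35.
#'
#' @param n_nodes Node count (needs >= 24 for the full default set; fewer
#'   pairs are planted on smaller graphs).
#' @param n_signal Number of planted edges (default 12).
#' @param beta Common edge coefficient (default -0.35).
#' @return data.frame with columns `i`, `j`, `beta`.
#' @export
default_signal_edges <- function(n_nodes, n_signal = 12L, beta = -0.35) {
  n_pairs <- min(n_signal, n_nodes %/% 2)
  i <- 2L * (seq_len(n_pairs) - 1L)
  data.frame(i = i, j = i + 1L, beta = rep(beta, n_pairs))
}

#' Paper-scale synthetic preset
#'
#' The full-size emulation: 677 subjects over 268 nodes (35,778 edges).
#'
#' @param ... Overrides passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
synthetic_spec_paper_scale <- function(...) {
  synthetic_spec(n_subjects = 677L, n_nodes = 268L,
                 signal_edges = default_signal_edges(268L), ...)
}

#' Generate a synthetic connectome-behavior dataset
#'
#' Draws scores from the score distribution (with optional confound
#' leakage), builds each signal edge as
#' `beta * standardized(score) + confound terms + N(0, noise_sd)`,
#' fills non-signal edges with pure `N(0, noise_sd)` noise on the
#' Fisher-z scale, generates the five-subscale emotion panel from a
#' one-factor model whose factor correlates with the score at the
#' configured level, draws mean FD so the configured fraction exceeds
#' 0.3, and masks panel cells at the missing rate. Deterministic given
#' the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `synthetic_dataset`: `dataset` (a
#'   [cpm_dataset()] with target `score` and confounds age, sex, mean_fd,
#'   negative_emotion), `panel` (subscales, with NAs where masked),
#'   `truth` (signal-edge table with edge-vector positions, generating
#'   loadings and effects, the latent factor and the complete panel),
#'   `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_subjects
  N <- spec$n_nodes
  E <- n_edges(N)

  with_seed(spec$seed, {
    # confounds
    age <- stats::rnorm(n, 19.94, 7.13)
    sex <- stats::rbinom(n, 1, 0.28)
    over <- stats::runif(n) < spec$fd_exceed_fraction
    fd <- pmin(pmax(stats::rnorm(n, spec$fd_mean, spec$fd_sd), 0), 0.3)
    fd[over] <- stats::runif(sum(over), 0.3 + 1e-6, 0.6)

    # latent emotion factor and score
    eta <- stats::rnorm(n)                       # base score innovation
    gl <- spec$confound_score_loadings
    zc <- cbind(age = scale_vec(age), sex = scale_vec(sex), mean_fd = scale_vec(fd))
    factor_raw <- spec$emotion_score_cor * eta +
      sqrt(max(0, 1 - spec$emotion_score_cor^2)) * stats::rnorm(n)
    z_all <- cbind(zc, negative_emotion = scale_vec(factor_raw))
    lam2 <- sum(gl[colnames(z_all)]^2)
    z_score <- drop(z_all %*% gl[colnames(z_all)]) + sqrt(max(0, 1 - lam2)) * eta
    score <- spec$score_mean + spec$score_sd * z_score

    # emotion panel from the one-factor model
    panel_means <- c(state_anxiety = 40.39, depression = 6.93,
                     perceived_stress = 17.07, negative_affect = 19.57,
                     loneliness = 41.76)
    panel_sds <- c(state_anxiety = 9.30, depression = 6.35,
                   perceived_stress = 4.72, negative_affect = 5.72,
                   loneliness = 7.48)
    lambda <- spec$emotion_loadings
    panel_z <- vapply(names(lambda), function(s) {
      lambda[[s]] * factor_raw + sqrt(max(0, 1 - lambda[[s]]^2)) * stats::rnorm(n)
    }, numeric(n))
    panel_full <- sweep(sweep(panel_z, 2, panel_sds[names(lambda)], "*"),
                        2, panel_means[names(lambda)], "+")
    colnames(panel_full) <- names(lambda)

    # edges
    X <- matrix(stats::rnorm(n * E, 0, spec$noise_sd), n, E)
    sig <- spec$signal_edges
    sig_idx <- integer(0)
    if (nrow(sig) > 0) {
      sig_idx <- edge_to_index(sig$i, sig$j, N)
      el <- spec$confound_edge_loadings
      conf_term <- drop(z_all %*% el[colnames(z_all)])
      for (k in seq_len(nrow(sig))) {
        X[, sig_idx[k]] <- X[, sig_idx[k]] + sig$beta[k] * z_score + conf_term
      }
    }

    # behavioral missingness on the panel
    panel <- panel_full
    if (spec$missing_rate > 0) {
      mask <- matrix(stats::runif(length(panel)) < spec$missing_rate,
                     nrow(panel), ncol(panel))
      # keep the imputation invariant satisfiable: never blank a full column
      for (j in seq_len(ncol(mask))) {
        if (sum(!mask[, j]) < 2) mask[seq_len(2), j] <- FALSE
      }
      panel[mask] <- NA_real_
    }

    behavior <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      score = score,
      age = age, sex = sex, mean_fd = fd,
      negative_emotion = drop(scale(panel_z) %*% lambda),
      stringsAsFactors = FALSE
    )
    ds <- cpm_dataset(X, behavior, N, target_name = "score",
                      confound_names = c("age", "sex", "mean_fd", "negative_emotion"))
    truth <- list(
      signal_edges = cbind(sig, edge_pos = sig_idx),
      emotion_loadings = lambda,
      emotion_factor = factor_raw,
      panel_complete = panel_full,
      confound_score_loadings = spec$confound_score_loadings,
      confound_edge_loadings = spec$confound_edge_loadings,
      z_score = z_score,
      seed = spec$seed
    )
    structure(list(dataset = ds, panel = as.data.frame(panel),
                   truth = truth, spec = spec),
              class = "synthetic_dataset")
  })
}

scale_vec <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d subjects, %d nodes, %d planted signal edges (seed %d)\n",
              x$spec$n_subjects, x$spec$n_nodes, nrow(x$spec$signal_edges), x$spec$seed))
  invisible(x)
}

#' Simulate node time series with a target correlation structure
#'
#' Draws T zero-mean Gaussian samples whose population correlation matrix
#' equals `tanh(target_fc)` (diagonal 1), so that the sample FC converges
#' to the target as T grows. Used to exercise the time-series-to-FC
#' stage with a known answer.
#'
#' @param target_fc An `fc_matrix` (Fisher-z scale); the implied
#'   correlation matrix must be positive definite.
#' @param n_timepoints T >= 3.
#' @param seed Integer seed.
#' @return A T x N numeric matrix of node time series.
#' @export
generate_timeseries <- function(target_fc, n_timepoints, seed = 1L) {
  if (!inherits(target_fc, "fc_matrix")) target_fc <- fc_matrix(target_fc)
  if (n_timepoints < 3) stop("need at least 3 timepoints")
  R <- tanh(unclass(target_fc))
  diag(R) <- 1
  L <- tryCatch(chol(R), error = function(e) {
    stop("target correlation matrix is not positive definite")
  })
  with_seed(seed, {
    matrix(stats::rnorm(n_timepoints * nrow(R)), n_timepoints) %*% L
  })
}

#' Synthetic atlas for an arbitrary node count
#'
#' Assigns nodes to the ten canonical macroscale regions in proportional
#' blocks, alternating hemispheres, with placeholder network labels and
#' coordinates. Purely structural scaffolding for simulated data.
#'
#' @param n_nodes Node count.
#' @return A `cpm_atlas`.
#' @export
synthetic_atlas <- function(n_nodes) {
  labels <- macroscale_regions()
  sizes <- diff(round(seq(0, n_nodes, length.out = length(labels) + 1)))
  as_cpm_atlas(data.frame(
    node_id = 0:(n_nodes - 1L),
    macroscale_region = rep(labels, times = sizes),
    functional_network = "n/a",
    hemisphere = rep_len(c("L", "R"), n_nodes),
    mni_x = 0, mni_y = 0, mni_z = 0,
    stringsAsFactors = FALSE
  ))
}

#' Load the packaged 268-node macroscale atlas fixture
#'
#' A synthetic stand-in for a 268-node whole-brain parcellation grouped
#' into ten macroscale regions with the published per-region node counts
#' (prefrontal 46, motor 21, insular 7, parietal 27, temporal 39,
#' occipital 25, limbic 36, cerebellum 41, subcortical 17, brainstem 9;
#' total 268). Node-to-region block assignment, hemispheres and
#' coordinates are synthetic placeholders, not the real parcellation.
#'
#' @return A `cpm_atlas` with 268 nodes.
#' @export
load_atlas268 <- function() {
  path <- system.file("extdata", "atlas268_synthetic.tsv", package = "cpmr",
                      mustWork = TRUE)
  read_atlas(path)
}

#' Write a synthetic dataset in the on-disk layout the pipeline consumes
#'
#' Writes one FC TSV per subject (`fc/<subject_id>.tsv`), `behavior.tsv`
#' (score, confounds and the emotion panel with missing cells blank),
#' `atlas.tsv`, and `ground_truth.json`.
#'
#' @param sd A [generate_dataset()] result.
#' @param out_dir Output directory.
#' @param atlas Atlas to write (default [synthetic_atlas()] at the spec's
#'   node count).
#' @return `out_dir`, invisibly.
#' @export
write_synthetic_dataset <- function(sd, out_dir, atlas = synthetic_atlas(sd$spec$n_nodes)) {
  stopifnot(inherits(sd, "synthetic_dataset"))
  dir.create(file.path(out_dir, "fc"), showWarnings = FALSE, recursive = TRUE)
  ds <- sd$dataset
  for (s in seq_len(nrow(ds$edge_matrix))) {
    fc <- devectorize_edges(ds$edge_matrix[s, ], ds$n_nodes)
    write_connectivity_matrix(fc, file.path(out_dir, "fc",
                                            paste0(ds$behavior$subject_id[s], ".tsv")))
  }
  beh <- cbind(ds$behavior, sd$panel)
  utils::write.table(beh, file.path(out_dir, "behavior.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(as.data.frame(atlas), file.path(out_dir, "atlas.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(signal_edges = sd$truth$signal_edges,
         emotion_loadings = as.list(sd$truth$emotion_loadings),
         seed = sd$truth$seed),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
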