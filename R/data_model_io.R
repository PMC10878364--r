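#' Read a subject connectivity matrix from a delimited file
#'
#' Reads a plain N x N numeric table (TSV by default), validates shape,
#' symmetry and finiteness, and returns a validated [fc_matrix()]. The
#' diagonal is ignored and stored as 0.
#'
#' @param path File path to a delimited N x N numeric table without header.
#' @param n_nodes Expected node count N.
#' @param sep Field separator (default tab).
#' @return An `fc_matrix`.
#' @export
read_connectivity_matrix <- function(path, n_nodes, sep = "\t") {
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", strip.white = TRUE)
  m <- suppressWarnings(apply(as.matrix(raw), c(1, 2), as.numeric))
  if (any(is.na(m))) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d, column %d of '%s'", idx[1], idx[2], path))
  }
  if (nrow(m) != n_nodes || ncol(m) != n_nodes) {
    stop(sprintf("dimension mismatch in '%s': expected %d x %d, got %d x %d",
                 path, n_nodes, n_nodes, nrow(m), ncol(m)))
  }
  dimnames(m) <- NULL
  fc_matrix(m)
}

#' Write an FC matrix as a plain TSV table
#' @param fc An `fc_matrix`.
#' @param path Output path.
#' @export
write_connectivity_matrix <- function(fc, path) {
  utils::write.table(format(unclass(fc), digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a behavioral table
#'
#' Reads a delimited table with a header containing a subject-id column,
#' the target score and any confound columns. Empty cells are kept as NA
#' (flagged missing), never dropped.
#'
#' @param path File path to a TSV with header.
#' @param target_name Name of the target-score column.
#' @param confound_names Character vector of confound column names (may be
#'   empty).
#' @param id_name Name of the subject-id column (default `"subject_id"`).
#' @return A data.frame with columns `subject_id` (character), the target
#'   and the confounds, one row per subject.
#' @export
read_behavior_table <- function(path, target_name, confound_names = character(),
                                id_name = "subject_id") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  need <- c(id_name, target_name, confound_names)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("missing required column(s) in '%s': %s", path, paste(miss, collapse = ", ")))
  }
  ids <- as.character(df[[id_name]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate subject id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (col in c(target_name, confound_names)) out[[col]] <- as.numeric(df[[col]])
  if (any(!is.na(out$mean_fd) & out$mean_fd < 0)) stop("mean_fd must be >= 0")
  out
}

#' Read an atlas definition table
#'
#' The atlas maps each node to a macroscale region, a functional network
#' label, a hemisphere and MNI coordinates. Node ids must be exactly
#' 0..N-1.
#'
#' @param path TSV with header columns `node_id`, `macroscale_region`,
#'   `functional_network`, `hemisphere`, `mni_x`, `mni_y`, `mni_z`.
#' @return A data.frame of class `cpm_atlas`, ordered by `node_id`.
#' @export
read_atlas <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_cpm_atlas(df)
}

#' Validate an atlas data.frame
#' @param df data.frame with the columns described in [read_atlas()].
#' @return The validated atlas, ordered by node id.
#' @export
as_cpm_atlas <- function(df) {
  need <- c("node_id", "macroscale_region", "functional_network",
            "hemisphere", "mni_x", "mni_y", "mni_z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop(sprintf("atlas missing column(s): %s", paste(miss, collapse = ", ")))
  df <- df[order(df$node_id), , drop = FALSE]
  n <- nrow(df)
  if (!identical(as.integer(df$node_id), 0:(n - 1L))) {
    stop("atlas node_id values must be exactly 0..N-1")
  }
  if (any(is.na(df$macroscale_region) | df$macroscale_region == "")) {
    stop("every atlas node needs a macroscale_region")
  }
  rownames(df) <- NULL
  class(df) <- c("cpm_atlas", "data.frame")
  df
}

#' The ten canonical macroscale region labels
#' @return Character vector of the ten macroscale brain-region labels in
#'   canonical order.
#' @export
macroscale_regions <- function() {
  c("prefrontal", "motor", "insular", "parietal", "temporal",
    "occipital", "limbic", "cerebellum", "subcortical", "brainstem")
}

#' Assemble a connectome dataset from matrices and behavioral records
#'
#' Vectorizes each subject's FC matrix (strict upper triangle, row-major)
#' and stacks the edge vectors into a subjects x edges design matrix in
#' behavioral-record order.
#'
#' @param matrices Named list of `fc_matrix` objects keyed by subject id.
#' @param behavior data.frame from [read_behavior_table()] (columns
#'   `subject_id`, target, confounds).
#' @param target_name Name of the target column in `behavior`.
#' @param confound_names Character vector naming confound columns.
#' @return An object of class `cpm_dataset` with elements `edge_matrix`
#'   (n x E), `behavior`, `n_nodes`, `target_name`, `confound_names`,
#'   `edge_order`.
#' @export
assemble_dataset <- function(matrices, behavior, target_name,
                             confound_names = character()) {
  if (nrow(behavior) == 0) stop("no subjects in behavioral table")
  ids <- behavior$subject_id
  absent <- setdiff(ids, names(matrices))
  if (length(absent) > 0) {
    stop(sprintf("no connectivity matrix for subject(s): %s", paste(absent, collapse = ", ")))
  }
  nn <- vapply(matrices[ids], nrow, integer(1))
  if (length(unique(nn)) != 1) {
    stop(sprintf("matrices differ in node count: %s", paste(unique(nn), collapse = ", ")))
  }
  N <- nn[[1]]
  X <- t(vapply(matrices[ids], vectorize_edges, numeric(n_edges(N))))
  rownames(X) <- ids
  cpm_dataset(X, behavior, N, target_name, confound_names)
}

#' Construct a `cpm_dataset` from an edge matrix directly
#'
#' @param edge_matrix n x E numeric matrix of Fisher-z edge values, rows in
#'   the order of `behavior` rows, columns per [edge_index()].
#' @param behavior Behavioral data.frame (`subject_id`, target, confounds).
#' @param n_nodes Node count N with `E = N(N-1)/2`.
#' @param target_name Target column name.
#' @param confound_names Confound column names.
#' @return A `cpm_dataset`.
#' @export
cpm_dataset <- function(edge_matrix, behavior, n_nodes, target_name,
                        confound_names = character()) {
  edge_matrix <- as.matrix(edge_matrix)
  if (nrow(edge_matrix) != nrow(behavior)) {
    stop("edge_matrix row count must equal behavioral record count")
  }
  if (ncol(edge_matrix) != n_edges(n_nodes)) {
    stop(sprintf("edge_matrix has %d columns; expected N(N-1)/2 = %d",
                 ncol(edge_matrix), n_edges(n_nodes)))
  }
  if (any(!is.finite(edge_matrix))) stop("edge values must all be finite")
  if (anyDuplicated(behavior$subject_id)) stop("duplicate subject ids")
  need <- c("subject_id", target_name, confound_names)
  miss <- setdiff(need, names(behavior))
  if (length(miss) > 0) stop(sprintf("behavior missing column(s): %s", paste(miss, collapse = ", ")))
  structure(list(
    edge_matrix = edge_matrix,
    behavior = behavior,
    n_nodes = as.integer(n_nodes),
    target_name = target_name,
    confound_names = confound_names,
    edge_order = "upper-triangle row-major, 0-based"
  ), class = "cpm_dataset")
}

#' @export
print.cpm_dataset <- function(x, ...) {
  cat(sprintf("<cpm_dataset> %d subjects, %d nodes, %d edges; target '%s'%s\n",
              nrow(x$edge_matrix), x$n_nodes, ncol(x$edge_matrix), x$target_name,
              if (length(x$confound_names)) {
                paste0("; confounds: ", paste(x$confound_names, collapse = ", "))
              } else ""))
  invisible(x)
}

#' Extract target scores from a dataset
#' @param dataset A `cpm_dataset`.
#' @return Numeric vector of target scores.
#' @export
dataset_scores <- function(dataset) dataset$behavior[[dataset$target_name]]

#' Extract the confound matrix from a dataset
#' @param dataset A `cpm_dataset`.
#' @return n x C numeric matrix (NULL when no confounds are declared).
#' @export
dataset_confounds <- function(dataset) {
  if (length(dataset$confound_names) == 0) return(NULL)
  as.matrix(dataset$behavior[dataset$confound_names])
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of a CPM run.
#'
#' @param selection_p_threshold Edge-selection p-value threshold (strict
#'   `p < threshold`; default 0.01).
#' @param cv_scheme `"loo"` or `"kfold"`.
#' @param k Folds for k-fold (default 10).
#' @param kfold_repeats Repetitions of the k-fold partition (default 100).
#' @param n_permutations Permutations for inference (default 1000; 0 skips
#'   the permutation test).
#' @param perm_kfold_repeats k-fold repetitions inside each permutation
#'   (default 10).
#' @param alpha Significance level (default 0.05).
#' @param confound_names Confounds controlled during selection and
#'   evaluation (empty = plain Pearson).
#' @param rng_seed Integer seed controlling partitioning and permutation.
#' @param fd_exclusion_threshold Mean-FD exclusion threshold in mm
#'   (default 0.3).
#' @param normalize_edges Z-score each edge across training subjects
#'   before computing strength (default FALSE; selection is unaffected
#'   because Pearson correlation is scale-invariant).
#' @return An object of class `cpm_config`.
#' @export
cpm_config <- function(selection_p_threshold = 0.01,
                       cv_scheme = c("loo", "kfold"),
                       k = 10L,
                       kfold_repeats = 100L,
                       n_permutations = 1000L,
                       perm_kfold_repeats = 10L,
                       alpha = 0.05,
                       confound_names = character(),
                       rng_seed = 1L,
                       fd_exclusion_threshold = 0.3,
                       normalize_edges = FALSE) {
  cv_scheme <- match.arg(cv_scheme)
  stopifnot(selection_p_threshold > 0, selection_p_threshold < 1,
            k >= 2, kfold_repeats >= 1, n_permutations >= 0,
            alpha > 0, alpha < 1, fd_exclusion_threshold >= 0)
  structure(list(
    selection_p_threshold = selection_p_threshold,
    cv_scheme = cv_scheme,
    k = as.integer(k),
    kfold_repeats = as.integer(kfold_repeats),
    n_permutations = as.integer(n_permutations),
    perm_kfold_repeats = as.integer(perm_kfold_repeats),
    alpha = alpha,
    confound_names = confound_names,
    rng_seed = as.integer(rng_seed),
    fd_exclusion_threshold = fd_exclusion_threshold,
    normalize_edges = isTRUE(normalize_edges)
  ), class = "cpm_config")
}

#' Write an edge mask (or weighted edge list) as TSV
#'
#' Columns: `node_i`, `node_j` (0-based, i < j) and `weight`. A header
#' comment line declares the vectorization convention.
#'
#' @param mask Logical vector over edges.
#' @param n_nodes Node count.
#' @param path Output path.
#' @param weights Optional numeric weights for masked edges (full-length
#'   edge vector; only masked entries are written).
#' @export
write_edge_mask <- function(mask, n_nodes, path, weights = NULL) {
  idx <- edge_index(n_nodes)
  sel <- which(mask)
  df <- data.frame(node_i = idx$i[sel], node_j = idx$j[sel],
                   weight = if (is.null(weights)) rep(1, length(sel)) else weights[sel])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# edge_order: upper-triangle row-major, 0-based", con)
  writeLines(sprintf("# n_nodes: %d", n_nodes), con)
  writeLines(paste(c("node_i", "node_j", "weight"), collapse = "\t"), con)
  if (nrow(df) > 0) {
    writeLines(paste(df$node_i, df$node_j,
                     format(df$weight, digits = 17, trim = TRUE), sep = "\t"), con)
  }
  invisible(path)
}

#' Read an edge mask written by [write_edge_mask()]
#' @param path Mask TSV path.
#' @param n_nodes Node count (checked against the file header).
#' @return List with `mask` (logical over edges) and `weights` (numeric,
#'   NA off-mask).
#' @export
read_edge_mask <- function(path, n_nodes) {
  lines <- readLines(path)
  hdr <- grep("^# n_nodes:", lines, value = TRUE)
  if (length(hdr) == 1) {
    n_file <- as.integer(sub("^# n_nodes:\\s*", "", hdr))
    if (n_file != n_nodes) stop(sprintf("mask file is for N=%d, expected N=%d", n_file, n_nodes))
  }
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = paste(body, collapse = "\n"), sep = "\t", header = TRUE)
  E <- n_edges(n_nodes)
  mask <- logical(E)
  weights <- rep(NA_real_, E)
  if (nrow(df) > 0) {
    pos <- edge_to_index(df$node_i, df$node_j, n_nodes)
    mask[pos] <- TRUE
    weights[pos] <- df$weight
  }
  list(mask = mask, weights = weights)
}

#' Map 0-based node pairs to edge-vector positions
#' @param i,j 0-based node indices with i < j.
#' @param n_nodes Node count.
#' @return 1-based positions into the canonical edge vector.
#' @export
edge_to_index <- function(i, j, n_nodes) {
  if (any(i >= j) || any(i < 0) || any(j >= n_nodes)) {
    stop("need 0 <= i < j < n_nodes")
  }
  # offset of row i = E - (N-i)(N-i-1)/2 edges before it
  as.integer(n_edges(n_nodes) - (n_nodes - i) * (n_nodes - i - 1) / 2 + (j - i))
}

#' Run the full CPM pipeline and write its artifacts
#'
#' Orchestrates edge selection, cross-validation, permutation inference,
#' contributing-network characterization and reporting for one dataset.
#' All randomness derives from `config$rng_seed`; two runs with identical
#' inputs produce byte-identical artifacts.
#'
#' @param dataset A `cpm_dataset`.
#' @param atlas A `cpm_atlas` covering the dataset's nodes.
#' @param config A [cpm_config()]. `config$confound_names` selects
#'   partial-correlation control; must be columns of the behavior table.
#' @param out_dir Output directory (created if needed). Set NULL to skip
#'   writing and return the report invisibly.
#' @return A list (the run report), invisibly when written to disk.
#' @export
run_pipeline <- function(dataset, atlas, config, out_dir = NULL) {
  stopifnot(inherits(dataset, "cpm_dataset"), inherits(config, "cpm_config"))
  if (!is.null(atlas) && nrow(atlas) != dataset$n_nodes) {
    stop(sprintf("stage atlas: atlas has %d nodes, dataset has %d", nrow(atlas), dataset$n_nodes))
  }
  if (length(config$confound_names) > 0) {
    dataset$confound_names <- config$confound_names
    miss <- setdiff(config$confound_names, names(dataset$behavior))
    if (length(miss) > 0) stop(sprintf("stage setup: confound column(s) missing: %s",
                                       paste(miss, collapse = ", ")))
  }

  cv <- tryCatch(
    if (config$cv_scheme == "loo") cpm_loocv(dataset, config) else cpm_kfold(dataset, config),
    error = function(e) stop(sprintf("stage cross-validation: %s", conditionMessage(e)), call. = FALSE)
  )

  perm <- NULL
  if (config$n_permutations > 0) {
    perm <- tryCatch(
      list(
        positive = permutation_test(dataset, config, cv, network = "positive"),
        negative = permutation_test(dataset, config, cv, network = "negative")
      ),
      error = function(e) stop(sprintf("stage permutation: %s", conditionMessage(e)), call. = FALSE)
    )
  }

  nets <- tryCatch({
    w <- full_sample_edge_weights(dataset)
    list(
      positive = contributing_network(cv$positive$fold_masks, w),
      negative = contributing_network(cv$negative$fold_masks, w)
    )
  }, error = function(e) stop(sprintf("stage contributing-network: %s", conditionMessage(e)), call. = FALSE))

  report <- list(
    package = "cpmr",
    config = unclass(config),
    n_subjects = nrow(dataset$edge_matrix),
    n_nodes = dataset$n_nodes,
    n_edges = ncol(dataset$edge_matrix),
    edge_order = dataset$edge_order,
    target = dataset$target_name,
    performance = list(
      positive = cv_performance_entry(cv$positive, perm$positive),
      negative = cv_performance_entry(cv$negative, perm$negative)
    ),
    fold_mask_sizes = list(
      positive = vapply(cv$positive$fold_masks, sum, integer(1)),
      negative = vapply(cv$negative$fold_masks, sum, integer(1))
    ),
    contributing_edges = list(
      positive = sum(nets$positive$edge_mask),
      negative = sum(nets$negative$edge_mask)
    ),
    degenerate_folds = list(
      positive = cv$positive$n_degenerate,
      negative = cv$negative$n_degenerate
    ),
    seed = config$rng_seed
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    N <- dataset$n_nodes
    preds <- data.frame(
      subject_id = dataset$behavior$subject_id,
      observed = dataset_scores(dataset),
      predicted_positive = cv$positive$predicted,
      predicted_negative = cv$negative$predicted
    )
    write_predictions(preds, file.path(out_dir, "predictions.tsv"))
    write_edge_mask(nets$positive$edge_mask, N, file.path(out_dir, "contributing_positive.tsv"),
                    nets$positive$edge_weight)
    write_edge_mask(nets$negative$edge_mask, N, file.path(out_dir, "contributing_negative.tsv"),
                    nets$negative$edge_weight)
    if (!is.null(atlas)) {
      for (side in c("positive", "negative")) {
        ns <- node_strength(nets[[side]], N)
        ns$region <- atlas$macroscale_region[ns$node_id + 1L]
        ns$network <- atlas$functional_network[ns$node_id + 1L]
        ns$hemisphere <- atlas$hemisphere[ns$node_id + 1L]
        utils::write.table(ns, file.path(out_dir, sprintf("node_strength_%s.tsv", side)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        mc <- macroscale_counts(nets[[side]], atlas)
        utils::write.table(mc, file.path(out_dir, sprintf("macroscale_counts_%s.tsv", side)),
                           sep = "\t", quote = FALSE, row.names = TRUE, col.names = NA)
      }
    }
    avg <- average_models(cv$negative$fold_models)
    jsonlite::write_json(
      avg[c("mean_slope", "mean_intercept", "mean_strength_mean",
            "mean_strength_sd", "mean_score_mean", "mean_score_sd",
            "n_models_averaged")],
      file.path(out_dir, "averaged_model.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(perm)) {
      nd <- data.frame(permutation = seq_along(perm$negative$null_distribution),
                       r_positive = perm$positive$null_distribution,
                       r_negative = perm$negative$null_distribution)
      utils::write.table(nd, file.path(out_dir, "null_distribution.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
    return(invisible(report))
  }
  report
}

cv_performance_entry <- function(cvr, permr) {
  list(
    r = cvr$performance_r,
    partial_r = if (is.null(cvr$performance_partial_r)) NULL else cvr$performance_partial_r,
    permutation_p = if (is.null(permr)) NULL else permr$p,
    permutation_p_raw = if (is.null(permr)) NULL else permr$p_raw
  )
}

#' Write an out-of-fold predictions table
#' @param preds data.frame with at least `subject_id` and `observed`.
#' @param path Output TSV path.
#' @export
write_predictions <- function(preds, path) {
  num <- vapply(preds, is.numeric, logical(1))
  out <- preds
  out[num] <- lapply(preds[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a predictions table written by [write_predictions()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_predictions <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
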