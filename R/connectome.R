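#' Fisher r-to-z transformation
#'
#' Variance-stabilizing transform `z = atanh(r)` applied to Pearson
#' correlation coefficients before they are treated as approximately
#' Gaussian edge values.
#'
#' @param r Numeric vector of correlations, each strictly inside (-1, 1).
#' @return Numeric vector of Fisher-z values, same length as `r`.
#' @examples
#' fisher_z(0.5)    # 0.5493
#' fisher_z(-0.9)   # -1.4722
#' @export
fisher_z <- function(r) {
  if (!is.numeric(r)) stop("'r' must be numeric")
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("fisher_z is defined only for |r| < 1")
  }
  atanh(r)
}

#' Inverse Fisher transformation
#'
#' @param z Numeric vector of Fisher-z values.
#' @return Correlations `tanh(z)`.
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Edge index table for the package-wide vectorization convention
#'
#' Edges are the strict upper triangle (i < j) of a symmetric node-by-node
#' matrix, enumerated row-major with 0-based node indices:
#' (0,1), (0,2), ..., (0,N-1), (1,2), ... This convention is fixed across
#' all functions and declared in every on-disk artifact.
#'
#' @param n_nodes Number of nodes N (>= 2).
#' @return A data.frame with integer columns `i`, `j` (0-based, i < j) and
#'   `N*(N-1)/2` rows.
#' @export
edge_index <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 2) stop("'n_nodes' must be an integer >= 2")
  i <- rep.int(seq_len(n_nodes - 1L) - 1L, times = (n_nodes - 1L):1L)
  j <- sequence((n_nodes - 1L):1L) + i
  data.frame(i = i, j = j)
}

#' Number of edges for N nodes
#' @param n_nodes Number of nodes.
#' @return `N*(N-1)/2`.
#' @export
n_edges <- function(n_nodes) as.integer(n_nodes * (n_nodes - 1) / 2)

#' Construct a validated FC matrix object
#'
#' An `fc_matrix` is a symmetric node-by-node matrix of Fisher-z
#' connectivity values with the diagonal fixed at 0.
#'
#' @param z N x N numeric matrix; must be symmetric to `tol` off the
#'   diagonal with all off-diagonal entries finite.
#' @param tol Symmetry tolerance (default 1e-8).
#' @return An object of class `fc_matrix`.
#' @export
fc_matrix <- function(z, tol = 1e-8) {
  if (!is.matrix(z) || !is.numeric(z)) stop("FC input must be a numeric matrix")
  n <- nrow(z)
  if (ncol(z) != n) stop(sprintf("FC matrix must be square, got %d x %d", n, ncol(z)))
  if (n < 2) stop("FC matrix needs at least 2 nodes")
  off <- z[row(z) != col(z)]
  if (any(!is.finite(off))) stop("FC matrix has non-finite off-diagonal values")
  d <- abs(z - t(z))
  bad <- which(d > tol, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    p <- bad[1, ]
    stop(sprintf(
      "FC matrix not symmetric: entries (%d,%d)=%g and (%d,%d)=%g differ (0-based nodes %d,%d)",
      p[1], p[2], z[p[1], p[2]], p[2], p[1], z[p[2], p[1]], p[1] - 1L, p[2] - 1L
    ))
  }
  z <- (z + t(z)) / 2
  diag(z) <- 0
  structure(z, class = c("fc_matrix", "matrix", "array"))
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %d nodes, %d edges (Fisher-z)\n", nrow(x), n_edges(nrow(x))))
  invisible(x)
}

#' Fisher-z connectivity from node time series
#'
#' Computes the Pearson correlation between every pair of node time
#' courses and applies the Fisher r-to-z transformation, yielding one
#' symmetric connectivity matrix per subject.
#'
#' @param ts Numeric T x N matrix: T timepoints (rows) by N node signals
#'   (columns). Requires T >= 3, finite values, and nonzero variance in
#'   every column.
#' @return An `fc_matrix` with `z[i,j] = atanh(cor(ts[,i], ts[,j]))` and a
#'   zero diagonal.
#' @export
timeseries_to_fc <- function(ts) {
  if (!is.matrix(ts) || !is.numeric(ts)) stop("'ts' must be a numeric matrix")
  if (nrow(ts) < 3) stop("need at least 3 timepoints")
  if (ncol(ts) < 2) stop("need at least 2 nodes")
  if (any(!is.finite(ts))) stop("time series contain non-finite values")
  v <- apply(ts, 2, stats::var)
  if (any(v == 0)) {
    stop(sprintf("zero-variance time series at node %d (0-based)", which(v == 0)[1] - 1L))
  }
  r <- stats::cor(ts)
  off <- abs(r[row(r) != col(r)])
  if (any(off >= 1 - 1e-15)) {
    idx <- which(abs(r) >= 1 - 1e-15 & row(r) != col(r), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "perfect correlation between distinct nodes %d and %d (0-based): Fisher z diverges",
      idx[1] - 1L, idx[2] - 1L
    ))
  }
  diag(r) <- 0
  fc_matrix(atanh(r))
}

#' Vectorize an FC matrix into the canonical edge vector
#'
#' @param fc An `fc_matrix` (or plain symmetric numeric matrix).
#' @return Numeric vector of length `N*(N-1)/2` in strict-upper-triangle
#'   row-major order (see [edge_index()]).
#' @export
vectorize_edges <- function(fc) {
  if (!inherits(fc, "fc_matrix")) fc <- fc_matrix(fc)
  tm <- t(unclass(fc))
  tm[lower.tri(tm)]
}

#' Rebuild a symmetric FC matrix from an edge vector
#'
#' Inverse of [vectorize_edges()]: `devectorize_edges(vectorize_edges(fc),
#' nrow(fc))` reproduces `fc` exactly.
#'
#' @param v Edge vector of length `n_nodes*(n_nodes-1)/2`.
#' @param n_nodes Number of nodes.
#' @return An `fc_matrix`.
#' @export
devectorize_edges <- function(v, n_nodes) {
  E <- n_edges(n_nodes)
  if (length(v) != E) {
    stop(sprintf("edge vector length %d != N(N-1)/2 = %d for N = %d", length(v), E, n_nodes))
  }
  m <- matrix(0, n_nodes, n_nodes)
  m[lower.tri(m)] <- v
  m <- m + t(m) # lower.tri fill is column-major = row-major upper of the transpose
  fc_matrix(m)
}
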