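#' Contributing network: the across-fold edge intersection
#'
#' The contributing network is the set of edges selected in every
#' cross-validation fold, carrying as weights the full-sample (partial)
#' correlations between each edge and the target.
#'
#' @param fold_masks List of logical edge masks, one per fold.
#' @param edge_weights Full-length numeric vector of per-edge weights
#'   (typically [full_sample_edge_weights()]).
#' @return An object of class `contributing_network`: `edge_mask`
#'   (logical), `edge_weight` (numeric, NA off-mask), `n_folds`.
#' @export
contributing_network <- function(fold_masks, edge_weights) {
  if (length(fold_masks) < 1) stop("need at least one fold mask")
  E <- length(fold_masks[[1]])
  len <- vapply(fold_masks, length, integer(1))
  if (any(len != E)) stop("fold masks differ in length")
  if (length(edge_weights) != E) stop("edge_weights length must match mask length")
  mask <- Reduce(`&`, fold_masks)
  w <- rep(NA_real_, E)
  w[mask] <- edge_weights[mask]
  if (any(!is.finite(w[mask]))) stop("contributing-edge weights must be finite")
  structure(list(edge_mask = mask, edge_weight = w, n_folds = length(fold_masks)),
            class = "contributing_network")
}

#' @export
print.contributing_network <- function(x, ...) {
  cat(sprintf("<contributing_network> %d edges present in all %d folds\n",
              sum(x$edge_mask), x$n_folds))
  invisible(x)
}

#' Node strength within a contributing network
#'
#' The strength of a node is the sum of the absolute weights of the
#' contributing-network edges incident to it (absolute values, since a
#' negative network has all-negative correlation weights). The signed sum
#' is also returned for transparency. The table is sorted by descending
#' strength with ties kept in node-id order.
#'
#' @param net A [contributing_network()].
#' @param n_nodes Number of nodes N.
#' @return data.frame with columns `node_id` (0-based), `strength`,
#'   `signed_strength`, `rank`.
#' @export
node_strength <- function(net, n_nodes) {
  stopifnot(inherits(net, "contributing_network"))
  if (length(net$edge_mask) != n_edges(n_nodes)) {
    stop("n_nodes inconsistent with the network's edge-space size")
  }
  idx <- edge_index(n_nodes)
  strength <- numeric(n_nodes)
  signed <- numeric(n_nodes)
  sel <- which(net$edge_mask)
  for (e in sel) {
    w <- net$edge_weight[e]
    a <- idx$i[e] + 1L; b <- idx$j[e] + 1L
    strength[a] <- strength[a] + abs(w)
    strength[b] <- strength[b] + abs(w)
    signed[a] <- signed[a] + w
    signed[b] <- signed[b] + w
  }
  out <- data.frame(node_id = 0:(n_nodes - 1L), strength = strength,
                    signed_strength = signed)
  out <- out[order(-out$strength, out$node_id), , drop = FALSE]
  out$rank <- seq_len(n_nodes)
  rownames(out) <- NULL
  out
}

#' Macroscale-region edge counts
#'
#' Counts contributing-network edges within and between the atlas's
#' macroscale regions. Within-region edges sit on the diagonal; the
#' matrix is symmetric and its upper triangle plus diagonal sums to the
#' number of masked edges.
#'
#' @param net A `contributing_network`.
#' @param atlas A `cpm_atlas` covering all nodes of the edge space.
#' @return Symmetric integer matrix with region labels as dimnames
#'   (canonical 10-label order first, then any extra labels).
#' @export
macroscale_counts <- function(net, atlas) {
  stopifnot(inherits(net, "contributing_network"))
  n_nodes <- nrow(atlas)
  if (length(net$edge_mask) != n_edges(n_nodes)) {
    stop("atlas does not cover the network's nodes")
  }
  regions <- atlas$macroscale_region
  labels <- c(intersect(macroscale_regions(), unique(regions)),
              setdiff(unique(regions), macroscale_regions()))
  counts <- matrix(0L, length(labels), length(labels), dimnames = list(labels, labels))
  idx <- edge_index(n_nodes)
  sel <- which(net$edge_mask)
  for (e in sel) {
    ra <- regions[idx$i[e] + 1L]
    rb <- regions[idx$j[e] + 1L]
    counts[ra, rb] <- counts[ra, rb] + 1L
    if (ra != rb) counts[rb, ra] <- counts[rb, ra] + 1L
  }
  counts
}

#' Compare two contributing networks over the same edge space
#'
#' Reports the shared edges (elementwise AND), the set-difference masks,
#' and the macroscale counts of the unique-to-A network (the "unique
#' contributing network" of outcome A relative to outcome B).
#'
#' @param net_a,net_b `contributing_network` objects with equal edge-space
#'   length.
#' @param atlas Optional `cpm_atlas` for macroscale counts of the unique
#'   networks.
#' @return List of class `network_comparison`: `shared_count`,
#'   `shared_mask`, `unique_a`, `unique_b` (masks), and when an atlas is
#'   given `macroscale_unique_a`, `macroscale_unique_b`.
#' @export
compare_networks <- function(net_a, net_b, atlas = NULL) {
  stopifnot(inherits(net_a, "contributing_network"),
            inherits(net_b, "contributing_network"))
  if (length(net_a$edge_mask) != length(net_b$edge_mask)) {
    stop("networks live in different edge spaces")
  }
  shared <- net_a$edge_mask & net_b$edge_mask
  ua <- net_a$edge_mask & !net_b$edge_mask
  ub <- net_b$edge_mask & !net_a$edge_mask
  out <- list(shared_count = sum(shared), shared_mask = shared,
              unique_a = ua, unique_b = ub)
  if (!is.null(atlas)) {
    mk_net <- function(mask, w) {
      structure(list(edge_mask = mask, edge_weight = ifelse(mask, w, NA_real_),
                     n_folds = 1L), class = "contributing_network")
    }
    out$macroscale_unique_a <- macroscale_counts(mk_net(ua, net_a$edge_weight), atlas)
    out$macroscale_unique_b <- macroscale_counts(mk_net(ub, net_b$edge_weight), atlas)
  }
  class(out) <- "network_comparison"
  out
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("<network_comparison> shared: %d, unique to A: %d, unique to B: %d\n",
              x$shared_count, sum(x$unique_a), sum(x$unique_b)))
  invisible(x)
}

#' Plot a macroscale count matrix as a simple heatmap
#'
#' @param counts Matrix from [macroscale_counts()].
#' @param main Plot title.
#' @export
plot_macroscale_counts <- function(counts, main = "Edges between macroscale regions") {
  k <- nrow(counts)
  graphics::image(seq_len(k), seq_len(k), t(counts[k:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "", main = main,
                  col = grDevices::hcl.colors(25, "YlOrRd", rev = TRUE))
  graphics::axis(1, at = seq_len(k), labels = colnames(counts), las = 2, cex.axis = 0.8)
  graphics::axis(2, at = seq_len(k), labels = rev(rownames(counts)), las = 2, cex.axis = 0.8)
  graphics::box()
  invisible(counts)
}
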