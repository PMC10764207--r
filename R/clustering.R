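# Cluster-count estimation (Louvain on the cell graph), embedding
# clustering (k-means) and the outer-loop convergence test.

#' Number of clusters by Louvain community detection
#'
#' Runs modularity-maximizing Louvain on the weighted cell graph (the
#' pruned pattern when available) and returns the community count. An
#' edgeless graph degenerates to one community per cell.
#'
#' @param g a `cell_graph` or a symmetric nonnegative adjacency matrix.
#' @param resolution Louvain resolution parameter.
#' @param seed RNG seed (Louvain's greedy sweep is randomized).
#' @return integer community count.
#' @export
louvain_k <- function(g, resolution = 1, seed = 1L) {
  W <- if (inherits(g, "cell_graph")) {
    if (!is.null(g$L0)) g$W * g$L0 else g$W
  } else g
  n <- nrow(W)
  if (n < 1L) stop_validation("empty graph")
  if (all(W == 0)) return(n)
  W <- (W + t(W)) / 2  # guard against floating-point asymmetry
  ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  set.seed(as.integer(seed))
  comm <- igraph::cluster_louvain(ig, resolution = resolution)
  length(unique(igraph::membership(comm)))
}

#' Cluster an embedding with seeded k-means
#'
#' Lloyd's algorithm with 10 seeded restarts, best within-cluster sum of
#' squares kept. Labels are relabelled by first occurrence so two runs
#' that find the same partition produce identical vectors.
#'
#' @param e cells-by-d embedding.
#' @param k number of clusters (`1 <= k <= n_cells`). If `k` exceeds the
#'   number of distinct rows it is reduced to that count.
#' @param seed RNG seed.
#' @param nstart restarts.
#' @return object of class `cluster_assignment`: list with integer
#'   `labels` (1-based, contiguous), `n_clusters`, `method`.
#' @export
kmeans_cluster <- function(e, k, seed = 1L, nstart = 10L) {
  if (!is.matrix(e)) e <- as.matrix(e)
  n <- nrow(e)
  k <- as.integer(k)
  if (k < 1L || k > n) stop_validation("k must satisfy 1 <= k <= n_cells")
  if (k == 1L) {
    labels <- rep(1L, n)
  } else if (k == n) {
    labels <- seq_len(n)
  } else {
    nd <- nrow(unique(e))
    if (k > nd) k <- nd
    set.seed(as.integer(seed))
    km <- kmeans(e, centers = k, nstart = nstart, iter.max = 100L)
    labels <- km$cluster
  }
  labels <- relabel_first_occurrence(labels)
  structure(list(labels = labels, n_clusters = length(unique(labels)),
                 method = "kmeans"),
            class = "cluster_assignment")
}

# canonical form: clusters numbered 1, 2, ... in order of first appearance
relabel_first_occurrence <- function(labels) {
  as.integer(match(labels, unique(labels)))
}

#' Outer-loop convergence by label agreement
#'
#' `TRUE` when the Adjusted Rand Index between the two assignments
#' reaches `ari_threshold`; invariant to relabelling either argument.
#'
#' @param prev,curr `cluster_assignment`s or plain label vectors of equal
#'   length.
#' @param ari_threshold agreement level treated as converged.
#' @return logical scalar.
#' @export
clustering_converged <- function(prev, curr, ari_threshold = 0.99) {
  a <- if (inherits(prev, "cluster_assignment")) prev$labels else prev
  b <- if (inherits(curr, "cluster_assignment")) curr$labels else curr
  if (length(a) != length(b)) stop_validation("label vectors differ in length")
  ari(a, b) >= ari_threshold
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment (%s): %d cells in %d clusters\n",
              x$method, length(x$labels), x$n_clusters))
  print(table(x$labels))
  invisible(x)
}
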