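# KNN cell graph: weighted adjacency over cells, per-node quantile
# pruning producing the 0/1 edge pattern L0, and the convex adjacency
# update used across outer iterations of the pipeline.

#' Build a K-nearest-neighbour cell graph
#'
#' Directed KNN by Euclidean distance on the embedding, symmetrized by
#' union. Edge weights are `1 / (1 + distance)`, so coincident cells get
#' weight 1; the diagonal is zero. Distance ties are broken by cell
#' index order.
#'
#' @param e cells-by-d embedding matrix.
#' @param k neighbours per cell (`1 <= k < n_cells`). The default
#'   `max(5, round(sqrt(n)))` adapts the neighbourhood size to the
#'   dataset.
#' @return object of class `cell_graph`: list with `n`, `W` (symmetric
#'   weight matrix), `D` (distances, `Inf` off-graph entries implicit via
#'   `W == 0`), `L0` (`NULL` until [prune_graph()]), `k`.
#' @export
build_knn_graph <- function(e, k = max(5L, round(sqrt(nrow(e))))) {
  if (!is.matrix(e)) e <- as.matrix(e)
  n <- nrow(e)
  if (n < 2L) stop_validation("need at least 2 cells")
  k <- as.integer(k)
  if (k < 1L || k >= n) stop_validation("k must satisfy 1 <= k < n_cells")
  D <- as.matrix(dist(e))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    nbr <- order(d, seq_len(n))[seq_len(k)]
    W[i, nbr] <- 1 / (1 + d[nbr])
  }
  W <- pmax(W, t(W))  # union symmetrization
  diag(W) <- 0
  dimnames(D) <- NULL
  if (!is.null(rownames(e))) dimnames(W) <- list(rownames(e), rownames(e))
  structure(list(n = n, W = W, D = D, L0 = NULL, k = k),
            class = "cell_graph")
}

#' Prune noisy edges of a cell graph
#'
#' Records as `L0` the 0/1 pattern of edges that survive per-node
#' distance-quantile thresholding: edge (i, j) is kept when its distance
#' is within the `quantile` threshold of either endpoint's incident
#' distances. Each node's shortest edge is always within its own
#' threshold, so no node is disconnected. The weighted adjacency `W` is
#' left untouched, which makes pruning idempotent.
#'
#' @param g a `cell_graph`.
#' @param quantile per-node distance quantile in (0, 1); edges longer
#'   than both endpoints' thresholds are dropped from `L0`.
#' @return `g` with `L0` set (symmetric 0/1 matrix, zero diagonal).
#' @export
prune_graph <- function(g, quantile = 0.9) {
  if (!inherits(g, "cell_graph")) stop_validation("g must be a cell_graph")
  if (quantile <= 0 || quantile >= 1) stop_validation("quantile must be in (0,1)")
  n <- g$n
  thr <- numeric(n)
  for (i in seq_len(n)) {
    inc <- which(g$W[i, ] > 0)
    # type 1 (inverted ECDF) returns an actual incident distance, so the
    # quantile -> 1 limit keeps every edge
    thr[i] <- if (length(inc)) stats::quantile(g$D[i, inc], probs = quantile,
                                               names = FALSE, type = 1) else 0
  }
  keep <- (g$W > 0) & (g$D <= outer(thr, rep(1, n)) | g$D <= outer(rep(1, n), thr))
  L0 <- matrix(0, n, n, dimnames = dimnames(g$W))
  L0[keep] <- 1
  diag(L0) <- 0
  g$L0 <- L0
  g$prune_quantile <- quantile
  g
}

#' One adjacency refinement step
#'
#' Convex blend of the pruned 0/1 pattern and the row-normalized weighted
#' adjacency:
#' `A_tilde = mu * L0 + (1 - mu) * A_ij / sum_j A_ij`,
#' optionally followed by symmetrization `(A_tilde + t(A_tilde)) / 2`.
#' Rows of `A` summing to zero contribute zero (isolated cells stay
#' isolated rather than becoming NaN).
#'
#' @param A nonnegative weighted adjacency.
#' @param L0 0/1 pruned adjacency of the same shape.
#' @param mu blend fraction in \[0, 1\]; `mu = 1` returns (symmetrized)
#'   `L0`, `mu = 0` the row-normalized `A`.
#' @param symmetrize average with the transpose after blending (the
#'   blend itself is row-wise and asymmetric).
#' @return refined adjacency matrix.
#' @export
iterate_adjacency <- function(A, L0, mu = 0.5, symmetrize = TRUE) {
  if (!all(dim(A) == dim(L0))) stop_validation("A and L0 shapes differ")
  if (any(A < 0) || any(L0 < 0)) stop_validation("adjacency entries must be nonnegative")
  if (mu < 0 || mu > 1) stop_validation("mu must be in [0, 1]")
  rs <- rowSums(A)
  norm <- A / ifelse(rs > 0, rs, 1)
  norm[rs == 0, ] <- 0
  out <- mu * L0 + (1 - mu) * norm
  if (symmetrize) out <- (out + t(out)) / 2
  out
}

#' Compare two adjacency matrices
#'
#' @param A1,A2 matrices of identical shape.
#' @param tol tolerance; `TRUE` iff `max(abs(A1 - A2)) <= tol`.
#' @return logical scalar.
#' @export
graphs_equal <- function(A1, A2, tol = 1e-4) {
  if (!all(dim(A1) == dim(A2))) stop_validation("shape mismatch")
  max(abs(A1 - A2)) <= tol
}

#' Edge list of a cell graph
#'
#' @param g a `cell_graph`.
#' @param pruned use the pruned pattern `L0` (if set) instead of all
#'   weighted edges.
#' @return data frame (cell_i, cell_j, weight), each undirected edge
#'   once.
#' @export
graph_edges <- function(g, pruned = FALSE) {
  W <- if (pruned && !is.null(g$L0)) g$W * g$L0 else g$W
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  ids <- rownames(W)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(W)))
  data.frame(cell_i = ids[idx[, 1L]], cell_j = ids[idx[, 2L]],
             weight = W[idx])
}

#' @export
print.cell_graph <- function(x, ...) {
  ne <- sum(x$W > 0) / 2
  cat(sprintf("cell_graph: %d cells, %d undirected edges (k = %d)%s\n",
              x$n, ne, x$k,
              if (!is.null(x$L0)) sprintf(", pruned to %d", sum(x$L0) / 2) else ""))
  invisible(x)
}
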