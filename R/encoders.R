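# The three dense-network stages: the feature auto-encoder that extracts
# a low-dimensional cell embedding from the expression matrix, the Tanh
# MLP encoder that further denoises that embedding, and the per-cluster
# auto-encoders that rebuild the expression matrix cluster by cluster.

#' Train the feature auto-encoder
#'
#' Symmetric dense auto-encoder (default path
#' `p -> 512 -> 128 -> 512 -> p`) minimizing the summed squared
#' reconstruction error `sum((X - Xhat)^2)`, optionally weighted
#' element-wise by TRS-derived weights. The 128-d bottleneck activation
#' is the cell embedding handed to the MLP encoder.
#'
#' @param x cells-by-genes expression matrix (log-normalized).
#' @param hidden encoder hidden sizes; the decoder mirrors them.
#' @param epochs,lr,seed training parameters (full-batch Adam).
#' @param trs_w optional cells-by-genes weight matrix in \[0, 1\] (see
#'   [trs_weights()]); when supplied the loss is
#'   `sum((X - Xhat)^2 * trs_w)`.
#' @return list with `embedding` (cells x bottleneck matrix),
#'   `reconstruction` (same shape as `x`), `net`, `loss_trace`.
#' @export
train_feature_ae <- function(x, hidden = c(512L, 128L), epochs = 500L,
                             lr = 1e-3, seed = 1L, trs_w = NULL) {
  validate_expression_matrix(x)
  p <- ncol(x)
  dims <- c(p, hidden, rev(hidden)[-1L], p)
  acts <- c(rep("relu", length(dims) - 2L), "none")
  net <- dense_net(dims, acts, seed = seed)
  w <- if (is.null(trs_w)) 1 else {
    if (!all(dim(trs_w) == dim(x))) stop_validation("trs_w shape mismatch")
    trs_w
  }
  n_entries <- length(x)
  grad_fn <- function(out) {
    r <- x - out
    list(loss = sum(w * r^2), d_out = -2 * w * r / n_entries)
  }
  tr <- nn_train(net, x, grad_fn, epochs = epochs, lr = lr)
  bottleneck <- length(hidden)
  emb <- nn_forward(tr$net, x, n_layers = bottleneck)
  rownames(emb) <- rownames(x)
  recon <- nn_forward(tr$net, x)
  dimnames(recon) <- dimnames(x)
  attr(recon, "log_transformed") <- attr(x, "log_transformed")
  list(embedding = emb, reconstruction = recon, net = tr$net,
       loss_trace = tr$loss_trace)
}

#' Build the 3-layer Tanh MLP encoder
#'
#' @param in_dim input (feature-AE embedding) dimension.
#' @param hidden sizes of the three Tanh layers (output last).
#' @param seed weight-init seed.
#' @return a `dense_net` whose layers are all Tanh.
#' @export
mlp_net <- function(in_dim, hidden = c(64L, 32L, 16L), seed = 1L) {
  dense_net(c(in_dim, hidden), rep("tanh", length(hidden)), seed = seed)
}

#' Apply the MLP encoder to an embedding
#'
#' Layer-wise `h = Tanh(W x + b)`; every output coordinate therefore lies
#' strictly in (-1, 1).
#'
#' @param e cells-by-d embedding matrix.
#' @param net a `dense_net` with Tanh activations throughout (see
#'   [mlp_net()]).
#' @return transformed embedding, rownames preserved.
#' @export
mlp_encode <- function(e, net) {
  if (!inherits(net, "dense_net")) stop_validation("net must be a dense_net")
  if (!all(net$activations == "tanh")) {
    stop_validation("MLP encoder layers must all use the Tanh activation")
  }
  if (ncol(e) != net$dims[1L]) stop_validation("embedding dimension mismatch")
  out <- nn_forward(net, e)
  rownames(out) <- rownames(e)
  out
}

#' Train the MLP encoder as a post-bottleneck refiner
#'
#' The MLP has no loss of its own in the model description, so by default
#' it is trained as the encoder half of a small auto-encoder that
#' reconstructs the feature-AE embedding (mode `"trained"`); mode
#' `"fixed"` skips training and uses the seeded random weights as a fixed
#' nonlinear projection.
#'
#' @param e cells-by-d embedding from the feature auto-encoder.
#' @param hidden Tanh layer sizes of the encoder half.
#' @param mode `"trained"` or `"fixed"`.
#' @param epochs,lr,seed training parameters.
#' @return list with `embedding` (MLP output), `net` (the Tanh encoder
#'   `dense_net`), `loss_trace`.
#' @export
train_mlp_encoder <- function(e, hidden = c(64L, 32L, 16L),
                              mode = c("trained", "fixed"),
                              epochs = 200L, lr = 1e-3, seed = 1L) {
  mode <- match.arg(mode)
  d <- ncol(e)
  enc <- mlp_net(d, hidden, seed = seed)
  if (mode == "trained") {
    dims <- c(d, hidden, rev(hidden)[-1L], d)
    acts <- c(rep("tanh", length(hidden)),
              rep("tanh", length(hidden) - 1L), "none")
    full <- dense_net(dims, acts, seed = seed)
    n_entries <- length(e)
    grad_fn <- function(out) {
      r <- e - out
      list(loss = sum(r^2), d_out = -2 * r / n_entries)
    }
    tr <- nn_train(full, e, grad_fn, epochs = epochs, lr = lr)
    enc$layers <- tr$net$layers[seq_along(hidden)]
    trace <- tr$loss_trace
  } else {
    trace <- numeric(0)
  }
  list(embedding = mlp_encode(e, enc), net = enc, loss_trace = trace)
}

#' Train one auto-encoder per cell cluster
#'
#' Each cluster's rows are reconstructed by an independently trained
#' auto-encoder; the per-cluster outputs are reassembled in the original
#' cell order, so the result has exactly the shape and ids of the input.
#' Singleton clusters are trained with the same specification (a
#' single-row fit is trivially easy; a warning-level log records it).
#'
#' @param x cells-by-genes matrix to rebuild (normally the feature-AE
#'   reconstruction).
#' @param labels integer cluster label per cell.
#' @param hidden,epochs,lr,seed per-cluster network parameters; cluster
#'   `k` trains with seed `seed + k`.
#' @param verbose log per-cluster sizes.
#' @return rebuilt cells-by-genes matrix.
#' @export
train_cluster_aes <- function(x, labels, hidden = c(128L, 64L), epochs = 200L,
                              lr = 1e-3, seed = 1L, verbose = FALSE) {
  validate_expression_matrix(x, allow_negative = TRUE)
  if (length(labels) != nrow(x)) stop_validation("one label per cell required")
  out <- x * NA_real_
  for (k in sort(unique(labels))) {
    rows <- which(labels == k)
    if (length(rows) == 1L) {
      scdgi_log(verbose, "cluster %s is a singleton", format(k))
    }
    xk <- x[rows, , drop = FALSE]
    hid <- pmin(hidden, max(2L, nrow(xk) * 2L))  # avoid absurd width for tiny clusters
    dims <- c(ncol(x), hid, rev(hid)[-1L], ncol(x))
    acts <- c(rep("relu", length(dims) - 2L), "none")
    net <- dense_net(dims, acts, seed = as.integer(seed) + as.integer(k))
    n_entries <- length(xk)
    grad_fn <- function(o) {
      r <- xk - o
      list(loss = sum(r^2), d_out = -2 * r / n_entries)
    }
    tr <- nn_train(net, xk, grad_fn, epochs = epochs, lr = lr)
    out[rows, ] <- nn_forward(tr$net, xk)
    scdgi_log(verbose, "cluster AE %s: %d cells, final loss %.4g",
              format(k), length(rows), tr$loss_trace[length(tr$loss_trace)])
  }
  dimnames(out) <- dimnames(x)
  attr(out, "log_transformed") <- attr(x, "log_transformed")
  out
}
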