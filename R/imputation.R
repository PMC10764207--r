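# Final imputation auto-encoder. Trained on the original (preprocessed)
# matrix with a reconstruction loss carrying four regularizers: the TRS
# state weights, an L1 penalty on network weights, the cell-graph
# quadratic penalty gamma1 * sum(A . (X - Xhat)^2) and the same-cluster
# penalty gamma2 * sum(B . (X - Xhat)^2), where "." is a matrix product
# and B is the 0/1 same-cluster indicator.

#' Same-cluster indicator matrix
#'
#' `B[i, j] = 1` iff cells i and j carry the same cluster label;
#' symmetric with unit diagonal.
#'
#' @param labels `cluster_assignment` or integer label vector.
#' @return 0/1 cells-by-cells matrix.
#' @export
build_indicator <- function(labels) {
  l <- if (inherits(labels, "cluster_assignment")) labels$labels else labels
  outer(l, l, "==") * 1
}

#' Imputation loss and its components
#'
#' `total = (1 - alpha) * sum(R) + alpha * sum(R * trs_w) +
#'  beta * w_l1 + gamma1 * sum(A %*% R) + gamma2 * sum(B %*% R)` with
#' `R = (X - Xhat)^2`. Note `sum(A %*% R)` weights each cell's residual
#' row by that cell's (column-)degree in `A`.
#'
#' @param x,xhat original and reconstructed matrices.
#' @param trs_w TRS weight matrix (same shape), or `NULL` when
#'   `alpha = 0`.
#' @param A,B cells-by-cells graph adjacency and cluster indicator (may
#'   be `NULL` when their strengths are 0).
#' @param w_l1 summed absolute network weights (scalar).
#' @param alpha,beta,gamma1,gamma2 regularization strengths
#'   (`alpha, beta` in \[0, 1\]; `gamma1, gamma2 >= 0`).
#' @return list `total`, `mse`, `trs`, `l1`, `graph`, `cluster`.
#' @export
imputation_loss <- function(x, xhat, trs_w = NULL, A = NULL, B = NULL,
                            w_l1 = 0, alpha = 0.5, beta = 0.5,
                            gamma1 = 0.1, gamma2 = 0.1) {
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1 || gamma1 < 0 || gamma2 < 0) {
    stop_validation("strengths out of range: alpha, beta in [0,1]; gammas >= 0")
  }
  if (!all(dim(x) == dim(xhat))) stop_validation("x and xhat shapes differ")
  R <- (x - xhat)^2
  mse <- sum(R)
  trs <- if (alpha > 0) {
    if (is.null(trs_w) || !all(dim(trs_w) == dim(x))) {
      stop_validation("alpha > 0 requires a TRS weight matrix of matching shape")
    }
    sum(R * trs_w)
  } else 0
  graph <- if (gamma1 > 0) {
    if (is.null(A)) stop_validation("gamma1 > 0 requires A")
    sum(A %*% R)
  } else 0
  cluster <- if (gamma2 > 0) {
    if (is.null(B)) stop_validation("gamma2 > 0 requires B")
    sum(B %*% R)
  } else 0
  total <- (1 - alpha) * mse + alpha * trs + beta * w_l1 +
    gamma1 * graph + gamma2 * cluster
  list(total = total, mse = mse, trs = trs, l1 = w_l1,
       graph = graph, cluster = cluster)
}

#' Train the imputation auto-encoder
#'
#' Minimizes [imputation_loss()] over a dense auto-encoder applied to the
#' original preprocessed matrix. Because `sum(A %*% R)` (and the B term)
#' reduce to per-cell row weights `colSums(A)[i]`, the residual gradient
#' is an element-wise reweighting; the L1 term adds `beta * sign(W)` to
#' every weight gradient. The returned matrix is clamped at zero.
#'
#' @param x cells-by-genes matrix (the original preprocessed GEM).
#' @param trs_w TRS weight matrix from [trs_weights()], or `NULL`.
#' @param A cells-by-cells graph adjacency (final iterated adjacency).
#' @param labels cluster assignment (vector or `cluster_assignment`).
#' @param alpha,beta,gamma1,gamma2 loss strengths, see
#'   [imputation_loss()].
#' @param hidden,epochs,lr,seed network and training parameters.
#' @return list with `imputed` (nonnegative matrix, same shape/ids as
#'   `x`), `net`, `loss_trace` (per-epoch total loss), `components`
#'   (final loss components).
#' @export
train_imputer <- function(x, trs_w = NULL, A = NULL, labels = NULL,
                          alpha = 0.5, beta = 0.5, gamma1 = 0.1, gamma2 = 0.1,
                          hidden = c(512L, 128L), epochs = 500L, lr = 1e-3,
                          seed = 1L) {
  validate_expression_matrix(x)
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1 || gamma1 < 0 || gamma2 < 0) {
    stop_validation("strengths out of range: alpha, beta in [0,1]; gammas >= 0")
  }
  n <- nrow(x); p <- ncol(x)
  B <- if (gamma2 > 0) {
    if (is.null(labels)) stop_validation("gamma2 > 0 requires cluster labels")
    build_indicator(labels)
  } else NULL
  if (gamma1 > 0 && is.null(A)) stop_validation("gamma1 > 0 requires A")
  if (alpha > 0 && is.null(trs_w)) stop_validation("alpha > 0 requires trs_w")

  # per-entry residual weight: (1-alpha) + alpha*T_ij + gamma1*cA_i + gamma2*cB_i
  w_entry <- matrix(1 - alpha, n, p)
  if (alpha > 0) w_entry <- w_entry + alpha * trs_w
  if (gamma1 > 0) w_entry <- w_entry + gamma1 * colSums(A)
  if (gamma2 > 0) w_entry <- w_entry + gamma2 * colSums(B)

  dims <- c(p, hidden, rev(hidden)[-1L], p)
  acts <- c(rep("relu", length(dims) - 2L), "none")
  net <- dense_net(dims, acts, seed = seed)
  n_entries <- length(x)

  env <- new.env()
  env$net <- net
  grad_fn <- function(out) {
    r <- x - out
    R <- r^2
    l1 <- nn_weight_l1(env$net)
    total <- sum(w_entry * R) + beta * l1
    list(loss = total, d_out = -2 * w_entry * r / n_entries)
  }
  # nn_train applies the L1 subgradient itself; keep env$net in sync so
  # the reported loss uses the current weights
  state <- .adam_init(net)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fwd <- nn_forward(net, x, cache = TRUE)
    env$net <- net
    g <- grad_fn(fwd$out)
    if (!is.finite(g$loss)) stop_divergence("imputation loss non-finite at epoch ", ep)
    trace[ep] <- g$loss
    bk <- .nn_backward(net, fwd, g$d_out)
    for (l in seq_along(bk$layers)) {
      bk$layers[[l]]$W <- bk$layers[[l]]$W +
        (beta / n_entries) * sign(net$layers[[l]]$W)
    }
    st <- .adam_step(net, state, bk$layers, lr, ep)
    net <- st$net
    state <- st$state
  }

  xhat <- nn_forward(net, x)
  imputed <- pmax(xhat, 0)
  dimnames(imputed) <- dimnames(x)
  attr(imputed, "log_transformed") <- attr(x, "log_transformed")
  comps <- imputation_loss(x, xhat, trs_w = trs_w, A = A, B = B,
                           w_l1 = nn_weight_l1(net), alpha = alpha,
                           beta = beta, gamma1 = gamma1, gamma2 = gamma2)
  list(imputed = imputed, net = net, loss_trace = trace, components = comps)
}
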