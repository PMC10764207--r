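# Minimal dense-network engine: seeded uniform fan-scaled init, forward
# pass, analytic backprop and full-batch Adam. All auto-encoders and the
# MLP encoder in the package are instances of this engine; training is
# deterministic for a fixed seed (full batch, no stochastic layers).

.act_fun <- function(z, act) {
  switch(act,
         tanh = tanh(z),
         relu = pmax(z, 0),
         sigmoid = plogis(z),
         none = z,
         stop_validation("unknown activation: ", act))
}

# derivative wrt pre-activation, expressed through output h where cheap
.act_grad <- function(z, h, act) {
  switch(act,
         tanh = 1 - h^2,
         relu = (z > 0) * 1,
         sigmoid = h * (1 - h),
         none = 1,
         stop_validation("unknown activation: ", act))
}

#' Create a dense feed-forward network
#'
#' @param layer_dims integer vector of layer sizes, input first; a network
#'   with `L + 1` entries has `L` weight layers.
#' @param activations character vector of length `L`, one of `"tanh"`,
#'   `"relu"`, `"sigmoid"`, `"none"` per layer.
#' @param seed integer seed for the uniform fan-scaled weight init.
#' @return object of class `dense_net`.
#' @export
dense_net <- function(layer_dims, activations, seed = 1L) {
  if (length(layer_dims) < 2L || any(layer_dims < 1L)) {
    stop_validation("layer_dims must list at least input and output sizes, all >= 1")
  }
  L <- length(layer_dims) - 1L
  if (length(activations) != L) {
    stop_validation("need one activation per weight layer (", L, ")")
  }
  set.seed(as.integer(seed))
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    d_in <- layer_dims[l]; d_out <- layer_dims[l + 1L]
    a <- sqrt(6 / (d_in + d_out))
    layers[[l]] <- list(W = matrix(runif(d_in * d_out, -a, a), d_in, d_out),
                        b = numeric(d_out))
  }
  structure(list(layers = layers, dims = layer_dims, activations = activations,
                 seed = as.integer(seed)),
            class = "dense_net")
}

#' Forward pass through a dense network
#'
#' @param net a `dense_net`.
#' @param x input matrix, samples in rows (`ncol(x)` must equal the input
#'   dimension).
#' @param n_layers stop after this many weight layers (default: all);
#'   lets callers read intermediate representations such as an
#'   auto-encoder bottleneck.
#' @param cache keep pre-activations for backprop.
#' @return output matrix, or (with `cache = TRUE`) a list `out`, `H`
#'   (activations per layer, input first), `Z` (pre-activations).
#' @export
nn_forward <- function(net, x, n_layers = length(net$layers), cache = FALSE) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != net$dims[1L]) stop_validation("input dimension mismatch")
  H <- vector("list", n_layers + 1L)
  Z <- vector("list", n_layers)
  H[[1L]] <- x
  for (l in seq_len(n_layers)) {
    Z[[l]] <- sweep(H[[l]] %*% net$layers[[l]]$W, 2L, net$layers[[l]]$b, "+")
    H[[l + 1L]] <- .act_fun(Z[[l]], net$activations[l])
  }
  if (cache) list(out = H[[n_layers + 1L]], H = H, Z = Z) else H[[n_layers + 1L]]
}

# backprop given gradient of the loss wrt the network output;
# returns per-layer W/b gradients and the gradient wrt the input
.nn_backward <- function(net, fwd, d_out) {
  L <- length(fwd$Z)
  grads <- vector("list", L)
  d <- d_out
  for (l in rev(seq_len(L))) {
    d <- d * .act_grad(fwd$Z[[l]], fwd$H[[l + 1L]], net$activations[l])
    grads[[l]] <- list(W = crossprod(fwd$H[[l]], d), b = colSums(d))
    d <- d %*% t(net$layers[[l]]$W)
  }
  list(layers = grads, d_input = d)
}

.adam_init <- function(net) {
  lapply(net$layers, function(ly) list(mW = ly$W * 0, vW = ly$W * 0,
                                       mb = ly$b * 0, vb = ly$b * 0))
}

.adam_step <- function(net, state, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (l in seq_along(net$layers)) {
    g <- grads[[l]]
    s <- state[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mW <- s$mW / (1 - beta1^t); vW <- s$vW / (1 - beta2^t)
    mb <- s$mb / (1 - beta1^t); vb <- s$vb / (1 - beta2^t)
    net$layers[[l]]$W <- net$layers[[l]]$W - lr * mW / (sqrt(vW) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b - lr * mb / (sqrt(vb) + eps)
    state[[l]] <- s
  }
  list(net = net, state = state)
}

#' Train a dense network by full-batch Adam
#'
#' @param net a `dense_net`.
#' @param x input matrix (samples in rows).
#' @param grad_fn function of the current output returning
#'   `list(loss = <scalar>, d_out = <gradient matrix>)`; the gradient
#'   should be on a mean (per-entry) scale for step-size stability.
#' @param epochs,lr training length and Adam learning rate.
#' @param l1 optional L1 penalty strength added to every weight gradient
#'   (subgradient `l1 * sign(W)`, same scale as `d_out`).
#' @return list `net` (trained), `loss_trace` (per-epoch loss as reported
#'   by `grad_fn`).
#' @export
nn_train <- function(net, x, grad_fn, epochs = 500L, lr = 1e-3, l1 = 0) {
  state <- .adam_init(net)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fwd <- nn_forward(net, x, cache = TRUE)
    g <- grad_fn(fwd$out)
    if (!is.finite(g$loss)) {
      stop_divergence("training loss became non-finite at epoch ", ep)
    }
    trace[ep] <- g$loss
    bk <- .nn_backward(net, fwd, g$d_out)
    if (l1 > 0) {
      for (l in seq_along(bk$layers)) {
        bk$layers[[l]]$W <- bk$layers[[l]]$W + l1 * sign(net$layers[[l]]$W)
      }
    }
    st <- .adam_step(net, state, bk$layers, lr, ep)
    net <- st$net
    state <- st$state
  }
  list(net = net, loss_trace = trace)
}

# sum of absolute weights across all layers (L1 norm of the network)
nn_weight_l1 <- function(net) {
  sum(vapply(net$layers, function(ly) sum(abs(ly$W)), numeric(1)))
}
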