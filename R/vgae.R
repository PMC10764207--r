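# Variational graph auto-encoder with multi-head graph attention.
#
# Encoder: two graph-attention convolutions (input -> 32 with ReLU, then
# parallel 32 -> 16 heads for the mean and log-sd of each cell's latent
# Gaussian). Attention scores are dot products of transformed features,
# e_ij = (W h_i) . (W h_j), passed through LeakyReLU and softmax over
# each node's neighbourhood; multiple heads are averaged. Latents are
# sampled as Z = mu + sigma * eps and the decoder reconstructs the
# adjacency as sigmoid(Z Z^T). Training minimizes dense cross-entropy
# plus a KL term against N(0, I). All gradients are analytic; training
# is full-batch Adam and deterministic for a fixed seed.

#' Specification of one graph-attention layer
#'
#' @param in_dim,out_dim feature dimensions.
#' @param n_heads number of attention heads; `0` disables attention
#'   (neighbours weighted uniformly by `1/|N(i)|`) but keeps a single
#'   weight matrix.
#' @param activation `"relu"` or `"none"`.
#' @param seed weight-init seed.
#' @return object of class `gat_spec` with a list `W` of
#'   `max(1, n_heads)` weight matrices.
#' @export
gat_spec <- function(in_dim, out_dim, n_heads = 1L, activation = c("relu", "none"),
                     seed = 1L) {
  activation <- match.arg(activation)
  if (n_heads < 0L) stop_validation("n_heads must be >= 0")
  set.seed(as.integer(seed))
  a <- sqrt(6 / (in_dim + out_dim))
  W <- lapply(seq_len(max(1L, n_heads)), function(k)
    matrix(runif(in_dim * out_dim, -a, a), in_dim, out_dim))
  structure(list(in_dim = in_dim, out_dim = out_dim, n_heads = as.integer(n_heads),
                 activation = activation, W = W, seed = as.integer(seed)),
            class = "gat_spec")
}

# edge list (src, dst) of a nonzero adjacency pattern, with a self-loop
# on every node so isolated nodes still propagate their own features
adjacency_edges <- function(adj, self_loops = TRUE) {
  idx <- which(adj > 0, arr.ind = TRUE)
  src <- idx[, 1L]; dst <- idx[, 2L]
  if (self_loops) {
    n <- nrow(adj)
    src <- c(src, seq_len(n))
    dst <- c(dst, seq_len(n))
  }
  ord <- order(src, dst)
  list(src = src[ord], dst = dst[ord], n = nrow(adj))
}

.leaky <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
.leaky_grad <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)

# stable per-source softmax over edge scores
.edge_softmax <- function(s, src, n) {
  grp <- factor(src, levels = seq_len(n))
  m <- unname(vapply(split(s, grp), function(v) if (length(v)) max(v) else 0,
                     numeric(1)))
  ex <- exp(s - m[src])
  denom <- as.numeric(rowsum(matrix(ex), grp))
  ex / denom[src]
}

#' Attention coefficients of one head
#'
#' Raw scores `e_ij = (W h_i) . (W h_j)` for every edge, normalized per
#' source node by softmax of `LeakyReLU(e_ij)` (negative slope 0.2), so
#' each node's coefficients sum to 1. With `uniform = TRUE` (the
#' zero-head ablation) every neighbour gets `1/|N(i)|` regardless of
#' features.
#'
#' @param h node feature matrix (nodes in rows).
#' @param W head weight matrix.
#' @param edges edge list as returned by `adjacency_edges` (list with
#'   integer vectors `src`, `dst` and node count `n`).
#' @param uniform disable attention.
#' @return list with per-edge `raw` scores and normalized `alpha`.
#' @export
attention_coeffs <- function(h, W, edges, uniform = FALSE) {
  if (max(edges$src, edges$dst) > nrow(h)) stop_validation("edge references unknown node")
  if (uniform) {
    deg <- tabulate(edges$src, nbins = edges$n)
    return(list(raw = rep(NA_real_, length(edges$src)),
                alpha = 1 / deg[edges$src]))
  }
  g <- h %*% W
  e <- rowSums(g[edges$src, , drop = FALSE] * g[edges$dst, , drop = FALSE])
  alpha <- .edge_softmax(.leaky(e), edges$src, edges$n)
  list(raw = e, alpha = alpha)
}

# forward pass of a GAT layer; cache holds per-head intermediates for
# backprop
gat_forward <- function(h, edges, spec, cache = FALSE) {
  if (ncol(h) != spec$in_dim) stop_validation("GAT input dimension mismatch")
  n <- edges$n
  K_eff <- max(1L, spec$n_heads)
  grp_src <- factor(edges$src, levels = seq_len(n))
  grp_dst <- factor(edges$dst, levels = seq_len(n))
  heads <- vector("list", K_eff)
  acc <- matrix(0, n, spec$out_dim)
  for (k in seq_len(K_eff)) {
    g <- h %*% spec$W[[k]]
    if (spec$n_heads == 0L) {
      deg <- tabulate(edges$src, nbins = n)
      alpha <- 1 / deg[edges$src]
      e <- NULL
    } else {
      e <- rowSums(g[edges$src, , drop = FALSE] * g[edges$dst, , drop = FALSE])
      alpha <- .edge_softmax(.leaky(e), edges$src, n)
    }
    M <- rowsum(alpha * g[edges$dst, , drop = FALSE], grp_src)
    acc <- acc + M
    heads[[k]] <- list(g = g, e = e, alpha = alpha)
  }
  pre <- acc / K_eff
  dimnames(pre) <- NULL  # rowsum() attaches group labels
  out <- .act_fun(pre, spec$activation)
  if (cache) list(out = out, pre = pre, heads = heads,
                  grp_src = grp_src, grp_dst = grp_dst)
  else out
}

#' Graph-attention convolution layer
#'
#' Aggregates each node's neighbourhood (self-loop included when the
#' edge list was built with them) with softmax-normalized attention,
#' averages heads and applies the activation.
#'
#' @param h node feature matrix.
#' @param adj adjacency (pattern) matrix, or an edge list from
#'   `adjacency_edges`.
#' @param spec a [gat_spec()].
#' @return transformed node feature matrix (`spec$out_dim` columns).
#' @export
gat_layer <- function(h, adj, spec) {
  edges <- if (is.list(adj) && !is.null(adj$src)) adj else adjacency_edges(adj)
  gat_forward(h, edges, spec)
}

# backprop: given d(loss)/d(out), return per-head dW and d(loss)/d(h)
gat_backward <- function(h, edges, spec, fw, d_out) {
  K_eff <- max(1L, spec$n_heads)
  dpre <- d_out * .act_grad(fw$pre, fw$out, spec$activation)
  dM <- dpre / K_eff
  dh <- matrix(0, nrow(h), ncol(h))
  dW <- vector("list", K_eff)
  src <- edges$src; dst <- edges$dst
  for (k in seq_len(K_eff)) {
    hd <- fw$heads[[k]]
    dg <- rowsum(hd$alpha * dM[src, , drop = FALSE], fw$grp_dst)
    if (spec$n_heads > 0L) {
      dalpha <- rowSums(dM[src, , drop = FALSE] * hd$g[dst, , drop = FALSE])
      S <- as.numeric(rowsum(matrix(hd$alpha * dalpha), fw$grp_src))
      ds <- hd$alpha * (dalpha - S[src])
      de <- ds * .leaky_grad(hd$e)
      dg <- dg + rowsum(de * hd$g[dst, , drop = FALSE], fw$grp_src) +
        rowsum(de * hd$g[src, , drop = FALSE], fw$grp_dst)
    }
    dW[[k]] <- crossprod(h, dg)
    dh <- dh + dg %*% t(spec$W[[k]])
  }
  list(dW = dW, dh = dh)
}

#' Forward pass of the variational graph auto-encoder
#'
#' @param features node feature matrix (cells in rows).
#' @param edges adjacency pattern matrix or edge list (self-loops are
#'   added when a matrix is given).
#' @param spec1 first GAT layer (input -> hidden, ReLU).
#' @param spec_mu,spec_sig parallel second layers producing the latent
#'   mean and log-sd (linear).
#' @param eps noise matrix (cells x latent dim) for the
#'   reparameterization `Z = mu + sigma * eps`; `NULL` uses `eps = 0`,
#'   i.e. the deterministic mean embedding.
#' @return list with `mu`, `sigma`, `Z`, `Ahat = sigmoid(Z Z^T)` and the
#'   forward caches used during training.
#' @export
vgae_forward <- function(features, edges, spec1, spec_mu, spec_sig, eps = NULL) {
  if (is.matrix(edges)) edges <- adjacency_edges(edges)
  f1 <- gat_forward(features, edges, spec1, cache = TRUE)
  fmu <- gat_forward(f1$out, edges, spec_mu, cache = TRUE)
  fsg <- gat_forward(f1$out, edges, spec_sig, cache = TRUE)
  logsig <- pmax(pmin(fsg$out, 10), -10)
  sigma <- exp(logsig)
  mu <- fmu$out
  if (is.null(eps)) eps <- matrix(0, nrow(mu), ncol(mu))
  Z <- mu + sigma * eps
  Ahat <- plogis(tcrossprod(Z))  # exactly symmetric
  if (any(!is.finite(Ahat))) stop_divergence("non-finite VGAE activations")
  list(mu = mu, sigma = sigma, Z = Z, Ahat = Ahat, eps = eps,
       cache = list(f1 = f1, fmu = fmu, fsg = fsg, logsig = logsig))
}

#' VGAE loss: dense cross-entropy plus KL to the standard normal
#'
#' `recon = -(1/N^2) * sum(a * log(ahat) + (1-a) * log(1-ahat))` with
#' `ahat` clipped to `[1e-7, 1 - 1e-7]`; `kl` is the per-node average of
#' `0.5 * sum(sigma^2 + mu^2 - 1 - 2 log sigma)`, zero exactly at
#' `mu = 0, sigma = 1`; `total = recon + kl_weight * kl`.
#'
#' @param A binary target adjacency.
#' @param Ahat reconstructed adjacency in (0, 1).
#' @param mu,sigma latent Gaussian parameters.
#' @param kl_weight KL term weight (the pipeline uses `1/n_cells`).
#' @return list `total`, `recon`, `kl`.
#' @export
vgae_loss <- function(A, Ahat, mu, sigma, kl_weight = 1) {
  if (!all(dim(A) == dim(Ahat))) stop_validation("A and Ahat shapes differ")
  ah <- pmin(pmax(Ahat, 1e-7), 1 - 1e-7)
  n2 <- length(A)
  recon <- -sum(A * log(ah) + (1 - A) * log(1 - ah)) / n2
  kl <- mean(0.5 * rowSums(sigma^2 + mu^2 - 1 - 2 * log(sigma)))
  list(total = recon + kl_weight * kl, recon = recon, kl = kl)
}

#' Train the variational graph auto-encoder
#'
#' Gradient-trains all attention-head weight matrices against the
#' [vgae_loss()] on the pruned cell graph. The returned embedding is the
#' deterministic latent mean `mu`.
#'
#' @param g a pruned `cell_graph` (needs `L0`), or a 0/1 adjacency
#'   matrix.
#' @param features node features (cells in rows), typically the MLP
#'   embedding.
#' @param dims hidden and latent dimensions of the two layers.
#' @param n_heads attention heads at both layers (0 disables attention).
#' @param epochs,lr,seed training parameters.
#' @param kl_weight weight of the KL term; default `1/n_cells`.
#' @return list with `embedding` (= final `mu`), `Ahat`, `loss_trace`,
#'   `specs`.
#' @export
train_vgae <- function(g, features, dims = c(32L, 16L), n_heads = 1L,
                       epochs = 200L, lr = 1e-3, seed = 1L, kl_weight = NULL) {
  A <- if (inherits(g, "cell_graph")) {
    if (is.null(g$L0)) stop_validation("graph must be pruned before VGAE training")
    g$L0
  } else g
  n <- nrow(A)
  target <- (A > 0) * 1
  diag(target) <- 1  # self-similarity is part of the reconstruction target
  edges <- adjacency_edges(target)
  if (is.null(kl_weight)) kl_weight <- 1 / n

  spec1 <- gat_spec(ncol(features), dims[1L], n_heads, "relu", seed = seed)
  spec_mu <- gat_spec(dims[1L], dims[2L], n_heads, "none", seed = seed + 1L)
  spec_sig <- gat_spec(dims[1L], dims[2L], n_heads, "none", seed = seed + 2L)

  params <- c(spec1$W, spec_mu$W, spec_sig$W)
  mstate <- lapply(params, function(w) list(m = w * 0, v = w * 0))
  K1 <- length(spec1$W); K2 <- length(spec_mu$W)

  set.seed(as.integer(seed))
  trace <- numeric(epochs)
  best <- NULL
  for (ep in seq_len(epochs)) {
    eps <- matrix(rnorm(n * dims[2L]), n, dims[2L])
    fw <- vgae_forward(features, edges, spec1, spec_mu, spec_sig, eps = eps)
    ls <- vgae_loss(target, fw$Ahat, fw$mu, fw$sigma, kl_weight)
    if (!is.finite(ls$total)) {
      if (!is.null(best)) {
        spec1$W <- best$W1; spec_mu$W <- best$Wmu; spec_sig$W <- best$Wsg
      }
      stop_divergence("VGAE loss became non-finite at epoch ", ep)
    }
    trace[ep] <- ls$total
    if (is.null(best) || ls$total <= min(trace[seq_len(ep)])) {
      best <- list(W1 = spec1$W, Wmu = spec_mu$W, Wsg = spec_sig$W)
    }

    # gradients
    dP <- (fw$Ahat - target) / length(target)
    dZ <- (dP + t(dP)) %*% fw$Z
    dmu <- dZ + kl_weight * fw$mu / n
    dsig <- dZ * eps + kl_weight * (fw$sigma - 1 / fw$sigma) / n
    dlogsig <- dsig * fw$sigma
    dlogsig[fw$cache$fsg$out != fw$cache$logsig] <- 0  # clipped region

    bk_mu <- gat_backward(fw$cache$f1$out, edges, spec_mu, fw$cache$fmu, dmu)
    bk_sg <- gat_backward(fw$cache$f1$out, edges, spec_sig, fw$cache$fsg, dlogsig)
    bk_1 <- gat_backward(features, edges, spec1, fw$cache$f1,
                         bk_mu$dh + bk_sg$dh)
    grads <- c(bk_1$dW, bk_mu$dW, bk_sg$dW)

    for (i in seq_along(params)) {
      st <- mstate[[i]]
      st$m <- 0.9 * st$m + 0.1 * grads[[i]]
      st$v <- 0.999 * st$v + 0.001 * grads[[i]]^2
      mh <- st$m / (1 - 0.9^ep); vh <- st$v / (1 - 0.999^ep)
      params[[i]] <- params[[i]] - lr * mh / (sqrt(vh) + 1e-8)
      mstate[[i]] <- st
    }
    spec1$W <- params[seq_len(K1)]
    spec_mu$W <- params[K1 + seq_len(K2)]
    spec_sig$W <- params[K1 + K2 + seq_len(K2)]
  }

  final <- vgae_forward(features, edges, spec1, spec_mu, spec_sig, eps = NULL)
  emb <- final$mu
  rownames(emb) <- rownames(features)
  list(embedding = emb, Ahat = final$Ahat, loss_trace = trace,
       specs = list(layer1 = spec1, mu = spec_mu, sigma = spec_sig))
}
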