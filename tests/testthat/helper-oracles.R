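# Independent brute-force oracles used to validate the package's metric
# and graph implementations. These deliberately use different code paths
# (explicit pair enumeration, permutation averaging, per-node loops)
# than the implementations they check.

# small labelled matrix builder
toy_matrix <- function(values, n_cells = nrow(values)) {
  as_expression_matrix(values,
                       paste0("c", seq_len(nrow(values))),
                       paste0("g", seq_len(ncol(values))))
}

# pair-counting over all C(n,2) element pairs
pair_counts_oracle <- function(x, y) {
  n <- length(x)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- x[i] == x[j]; sy <- y[i] == y[j]
      if (sx && sy) tp <- tp + 1
      else if (sx && !sy) fp <- fp + 1
      else if (!sx && sy) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

fms_oracle <- function(x, y) {
  pc <- pair_counts_oracle(x, y)
  if (pc$tp + pc$fp == 0 || pc$tp + pc$fn == 0) return(0)
  pc$tp / sqrt((pc$tp + pc$fp) * (pc$tp + pc$fn))
}

# entropies and MI by explicit double loop over label values
mi_oracle <- function(x, y) {
  n <- length(x)
  ux <- unique(x); uy <- unique(y)
  hx <- 0
  for (u in ux) { p <- sum(x == u) / n; hx <- hx - p * log(p) }
  hy <- 0
  for (v in uy) { p <- sum(y == v) / n; hy <- hy - p * log(p) }
  mi <- 0
  for (u in ux) for (v in uy) {
    pij <- sum(x == u & y == v) / n
    if (pij > 0) mi <- mi + pij * log(pij / ((sum(x == u) / n) * (sum(y == v) / n)))
  }
  list(mi = mi, hx = hx, hy = hy)
}

# all permutations of seq_len(n), recursively (n <= 7 in tests)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# exact expected MI under the permutation model, by enumeration
expected_mi_perm_oracle <- function(x, y) {
  perms <- all_perms(length(y))
  mean(vapply(perms, function(p) mi_oracle(x, y[p])$mi, numeric(1)))
}

ami_perm_oracle <- function(x, y) {
  o <- mi_oracle(x, y)
  if (o$hx == 0 && o$hy == 0) return(1)
  emi <- expected_mi_perm_oracle(x, y)
  denom <- (o$hx + o$hy) / 2 - emi
  if (abs(denom) < 1e-12) return(0)
  (o$mi - emi) / denom
}

# all labelings of n elements using at most k cluster ids
all_labelings <- function(n, k) {
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}

# per-node loop implementation of one GAT layer (no vectorization)
gat_layer_oracle <- function(h, adj, spec, slope = 0.2) {
  n <- nrow(h)
  K_eff <- max(1L, spec$n_heads)
  nbrs <- lapply(seq_len(n), function(i) sort(unique(c(which(adj[i, ] > 0), i))))
  acc <- matrix(0, n, spec$out_dim)
  for (k in seq_len(K_eff)) {
    g <- h %*% spec$W[[k]]
    for (i in seq_len(n)) {
      js <- nbrs[[i]]
      if (spec$n_heads == 0L) {
        a <- rep(1 / length(js), length(js))
      } else {
        e <- vapply(js, function(j) sum(g[i, ] * g[j, ]), numeric(1))
        s <- ifelse(e > 0, e, slope * e)
        a <- exp(s - max(s)); a <- a / sum(a)
      }
      for (t in seq_along(js)) acc[i, ] <- acc[i, ] + a[t] * g[js[t], ]
    }
  }
  pre <- acc / K_eff
  if (spec$activation == "relu") pmax(pre, 0) else pre
}

# brute-force KNN graph on small point sets
knn_oracle <- function(e, k) {
  n <- nrow(e)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(e) - e[i, ])^2))
    d[i] <- Inf
    nbr <- order(d, seq_len(n))[seq_len(k)]
    W[i, nbr] <- 1 / (1 + d[nbr])
  }
  W <- pmax(W, t(W))
  diag(W) <- 0
  W
}
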