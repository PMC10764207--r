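# Graph attention and the variational graph auto-encoder.

test_that("attention coefficients follow the dot-product / softmax law", {
  # identical features (1,2) with identity W give raw score 5 on any edge
  h <- rbind(c(1, 2), c(1, 2))
  ed <- scDGI:::adjacency_edges(matrix(c(0, 1, 1, 0), 2, 2), self_loops = FALSE)
  ac <- attention_coeffs(h, diag(2), ed)
  expect_equal(ac$raw, c(5, 5))

  # equal raw scores to m neighbours -> uniform 1/m
  n <- 5L
  A <- matrix(1, n, n); diag(A) <- 0
  hh <- matrix(1, n, 3)
  ed2 <- scDGI:::adjacency_edges(A, self_loops = FALSE)
  ac2 <- attention_coeffs(hh, matrix(rnorm(9), 3, 3), ed2)
  expect_equal(ac2$alpha, rep(1 / (n - 1), length(ed2$src)))

  # zero-head ablation ignores features entirely
  set.seed(31)
  hr <- matrix(rnorm(n * 3), n, 3)
  acu <- attention_coeffs(hr, diag(3), ed2, uniform = TRUE)
  expect_equal(acu$alpha, rep(1 / (n - 1), length(ed2$src)))
})

test_that("attention normalizes to one over every neighbourhood and head", {
  set.seed(32)
  n <- 12L
  A <- (matrix(runif(n * n), n, n) > 0.6) * 1
  A <- pmax(A, t(A)); diag(A) <- 0
  ed <- scDGI:::adjacency_edges(A)  # with self-loops
  h <- matrix(rnorm(n * 4), n, 4)
  for (k in 1:3) {
    sp <- gat_spec(4L, 6L, n_heads = k, seed = k)
    for (W in sp$W) {
      a <- attention_coeffs(h, W, ed)$alpha
      sums <- as.numeric(rowsum(matrix(a), factor(ed$src, levels = seq_len(n))))
      expect_equal(sums, rep(1, n), tolerance = 1e-6)
    }
  }
})

test_that("a self-loop-only node returns its activated transform", {
  sp <- gat_spec(2L, 2L, n_heads = 1L, activation = "relu", seed = 1L)
  sp$W[[1L]] <- diag(2)
  h <- matrix(c(1.5, -0.5), 1, 2)
  out <- gat_layer(h, matrix(0, 1, 1), sp)
  expect_equal(out, matrix(pmax(h, 0), 1, 2))
})

test_that("identical isolated pairs produce identical outputs (equivariance)", {
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 1
  A[3, 4] <- A[4, 3] <- 1
  h <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  sp <- gat_spec(2L, 3L, n_heads = 2L, activation = "relu", seed = 2L)
  out <- gat_layer(h, A, sp)
  expect_equal(out[1, ], out[3, ])
  expect_equal(out[2, ], out[4, ])
})

test_that("gat_layer matches the per-node loop oracle on small graphs", {
  for (s in 1:4) {
    set.seed(s)
    n <- sample(4:10, 1)
    A <- (matrix(runif(n * n), n, n) > 0.5) * 1
    A <- pmax(A, t(A)); diag(A) <- 0
    h <- matrix(rnorm(n * 3), n, 3)
    for (heads in c(0L, 1L, 3L)) {
      sp <- gat_spec(3L, 4L, n_heads = heads,
                     activation = if (s %% 2) "relu" else "none", seed = s)
      expect_equal(gat_layer(h, A, sp), gat_layer_oracle(h, A, sp),
                   tolerance = 1e-10)
    }
  }
})

test_that("a 3-node path with hand-set 1-d weights matches direct evaluation", {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  h <- matrix(c(1, 2, 3), 3, 1)
  sp <- gat_spec(1L, 1L, n_heads = 1L, activation = "none", seed = 1L)
  sp$W[[1L]] <- matrix(2, 1, 1)  # g = 2h
  # node 2 neighbours {1,2,3}: raw e = 4h2*hj = (8,16,24); softmax of
  # LeakyReLU(e) then weighted sum of g
  g <- 2 * c(1, 2, 3)
  e <- g[2] * g
  a <- exp(e - max(e)); a <- a / sum(a)
  expected2 <- sum(a * g)
  out <- gat_layer(h, A, sp)
  expect_equal(out[2, 1], expected2, tolerance = 1e-12)
})

test_that("the reparameterized latent and decoder obey their identities", {
  set.seed(33)
  n <- 6L
  A <- (matrix(runif(n * n), n, n) > 0.5) * 1
  A <- pmax(A, t(A)); diag(A) <- 0
  feats <- matrix(rnorm(n * 3), n, 3)
  s1 <- gat_spec(3L, 4L, 1L, "relu", seed = 1L)
  smu <- gat_spec(4L, 2L, 1L, "none", seed = 2L)
  ssg <- gat_spec(4L, 2L, 1L, "none", seed = 3L)
  # eps = NULL (sigma * 0): Z = mu exactly
  fw <- vgae_forward(feats, A, s1, smu, ssg, eps = NULL)
  expect_identical(fw$Z, fw$mu)
  expect_true(all(fw$sigma > 0))
  # Ahat is symmetric with entries in (0,1)
  expect_equal(fw$Ahat, t(fw$Ahat))
  expect_true(all(fw$Ahat > 0 & fw$Ahat < 1))
  # Z = 0 gives Ahat = 0.5 everywhere
  expect_equal(plogis(matrix(0, 2, 2) %*% t(matrix(0, 2, 2))),
               matrix(0.5, 2, 2))
})

test_that("the VGAE loss matches closed forms and its KL is a true divergence", {
  A <- matrix(0, 2, 2)
  Ahat <- matrix(0.5, 2, 2)
  mu <- matrix(0, 2, 2); sg <- matrix(1, 2, 2)
  ls <- vgae_loss(A, Ahat, mu, sg, kl_weight = 1)
  expect_equal(ls$recon, log(2), tolerance = 1e-6)
  expect_equal(ls$kl, 0)
  # perfect reconstruction limit
  ls2 <- vgae_loss(A, matrix(1e-7, 2, 2), mu, sg)
  expect_lt(ls2$recon, 1e-6)
  # KL nonnegative over random parameters, zero only at (0, 1)
  set.seed(34)
  for (i in 1:20) {
    m <- matrix(rnorm(4), 2, 2); s <- matrix(exp(rnorm(4)), 2, 2)
    expect_gte(vgae_loss(A, Ahat, m, s)$kl, 0)
  }
  expect_gt(vgae_loss(A, Ahat, mu + 0.5, sg)$kl, 0)
  expect_gt(vgae_loss(A, Ahat, mu, sg * 2)$kl, 0)
})

test_that("training separates two cliques and is deterministic per seed", {
  set.seed(35)
  n <- 16L
  A <- matrix(0, n, n)
  A[1:8, 1:8] <- 1; A[9:16, 9:16] <- 1; diag(A) <- 0
  feats <- rbind(matrix(rnorm(8 * 4, 2), 8, 4), matrix(rnorm(8 * 4, -2), 8, 4))
  vg <- train_vgae(A, feats, dims = c(8L, 4L), n_heads = 3L, epochs = 150L,
                   lr = 1e-2, seed = 5L)
  within <- mean(c(vg$Ahat[1:8, 1:8][upper.tri(diag(8))],
                   vg$Ahat[9:16, 9:16][upper.tri(diag(8))]))
  between <- mean(vg$Ahat[1:8, 9:16])
  expect_gt(within, between)
  expect_lte(vg$loss_trace[length(vg$loss_trace)], vg$loss_trace[1L])
  vg2 <- train_vgae(A, feats, dims = c(8L, 4L), n_heads = 3L, epochs = 150L,
                    lr = 1e-2, seed = 5L)
  expect_identical(vg$embedding, vg2$embedding)
  # ablation smoke: attention off still trains
  vg0 <- train_vgae(A, feats, dims = c(8L, 4L), n_heads = 0L, epochs = 30L, seed = 1L)
  expect_true(all(is.finite(vg0$embedding)))
})
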