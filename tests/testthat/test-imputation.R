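# Same-cluster indicator, regularized imputation loss, imputer training.

test_that("the same-cluster indicator matches its definition", {
  B <- build_indicator(c(0L, 0L, 1L))
  expect_equal(B, rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))
  expect_equal(build_indicator(rep(2L, 4)), matrix(1, 4, 4))
  expect_equal(build_indicator(1:4), diag(4))
  expect_equal(B, t(B))
  expect_true(all(diag(B) == 1))
})

test_that("the imputation loss reduces correctly at its corners", {
  x <- toy_matrix(rbind(c(1, 0), c(0, 1)))
  # perfect reconstruction, no weights: everything vanishes
  l0 <- imputation_loss(x, x, w_l1 = 0, alpha = 0, beta = 0,
                        gamma1 = 0, gamma2 = 0)
  expect_equal(l0$total, 0)
  # alpha = beta = gamma = 0 reduces to the plain squared-error sum
  xh <- x * 0
  l1 <- imputation_loss(x, xh, alpha = 0, beta = 0, gamma1 = 0, gamma2 = 0)
  expect_equal(l1$total, sum((x - xh)^2))
})

test_that("the graph term uses a true matrix product (hand-computed toy)", {
  x <- toy_matrix(rbind(c(1, 0), c(0, 1)))
  xh <- x * 0
  A <- rbind(c(0, 1), c(1, 0))
  l <- imputation_loss(x, xh, A = A, alpha = 0, beta = 0, gamma1 = 1, gamma2 = 0)
  # R = I; sum(R) = 2; sum(A %*% R) = sum(A) = 2; total = 2 + 2 = 4
  expect_equal(l$mse, 2)
  expect_equal(l$graph, 2)
  expect_equal(l$total, 4)
})

test_that("loss components are nonnegative and recompose into the total", {
  set.seed(51)
  x <- toy_matrix(matrix(runif(30, 0, 3), 6, 5))
  xh <- unclass(x) + matrix(rnorm(30, 0, 0.3), 6, 5)
  trs <- matrix(runif(30), 6, 5)
  A <- matrix(runif(36), 6, 6); A <- pmax(A, t(A)); diag(A) <- 0
  B <- build_indicator(c(1, 1, 2, 2, 3, 3))
  l <- imputation_loss(x, xh, trs_w = trs, A = A, B = B, w_l1 = 4.2,
                       alpha = 0.4, beta = 0.2, gamma1 = 0.3, gamma2 = 0.1)
  expect_true(all(unlist(l) >= 0))
  expect_equal(l$total,
               0.6 * l$mse + 0.4 * l$trs + 0.2 * l$l1 + 0.3 * l$graph + 0.1 * l$cluster,
               tolerance = 1e-8)
  expect_error(imputation_loss(x, xh, alpha = 1.5), class = "scdgi_validation_error")
  expect_error(imputation_loss(x, xh, gamma1 = -1), class = "scdgi_validation_error")
})

# shared small imputation scenario: 3 clusters, 10% dropout
imputation_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_cells(n_cells = 90, n_genes = 120, n_clusters = 3,
                            separation = 3, dropout_logit_scale = 0.8, seed = 5)
      xp <- log_normalize(sim$counts)
      dr <- simulate_dropout(xp, rate = 0.1, seed = 6L)
      g <- prune_graph(build_knn_graph(log1p(sim$truth), k = 9L))
      A <- iterate_adjacency(g$W, g$L0, mu = 0.5)
      cache <<- list(sim = sim, xp = xp, dr = dr, A = A, labels = sim$labels)
    }
    cache
  }
})

test_that("the trained imputer beats the zero baseline at masked entries", {
  fx <- imputation_fixture()
  lt <- ltmg_fit(fx$dr$matrix, k_max = 2L, max_iter = 60L)
  ti <- train_imputer(fx$dr$matrix, trs_w = trs_weights(lt), A = fx$A,
                      labels = fx$labels, hidden = c(64L, 32L),
                      epochs = 80L, seed = 2L)
  truth_v <- fx$dr$mask$value
  imp_v <- masked_values(ti$imputed, fx$dr$mask)
  rmse_model <- sqrt(mean((truth_v - imp_v)^2))
  rmse_zero <- sqrt(mean(truth_v^2))
  expect_lt(rmse_model, rmse_zero)
  # imputed values correlate positively with the truth they recover
  expect_gt(cor(truth_v, imp_v), 0)
  # contract: shape, ids, nonnegativity, determinism
  expect_identical(dimnames(ti$imputed), dimnames(fx$dr$matrix))
  expect_true(all(ti$imputed >= 0))
})

test_that("strong L1 shrinks the network weight norm", {
  fx <- imputation_fixture()
  t0 <- train_imputer(fx$dr$matrix, alpha = 0, beta = 0, gamma1 = 0, gamma2 = 0,
                      hidden = c(32L, 16L), epochs = 60L, seed = 3L)
  t1 <- train_imputer(fx$dr$matrix, alpha = 0, beta = 1, gamma1 = 0, gamma2 = 0,
                      hidden = c(32L, 16L), epochs = 60L, seed = 3L)
  expect_lt(scDGI:::nn_weight_l1(t1$net), scDGI:::nn_weight_l1(t0$net))
})

test_that("with all regularizers off the imputer matches a plain feature AE", {
  fx <- imputation_fixture()
  ti <- train_imputer(fx$dr$matrix, alpha = 0, beta = 0, gamma1 = 0, gamma2 = 0,
                      hidden = c(32L, 16L), epochs = 40L, seed = 9L)
  fa <- train_feature_ae(fx$dr$matrix, hidden = c(32L, 16L), epochs = 40L,
                         seed = 9L)
  expect_equal(ti$loss_trace, fa$loss_trace, tolerance = 1e-10)
})
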