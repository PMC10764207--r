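# KNN graph construction, quantile pruning, adjacency refinement.

test_that("KNN at k = 1 on two tight pairs keeps exactly the intra-pair edges", {
  e <- matrix(c(0, 0, 0.1, 0, 10, 0, 10.1, 0), ncol = 2, byrow = TRUE)
  g <- build_knn_graph(e, k = 1L)
  expected <- matrix(0, 4, 4)
  expected[1, 2] <- expected[2, 1] <- 1 / 1.1
  expected[3, 4] <- expected[4, 3] <- 1 / 1.1
  expect_equal(g$W, expected)
})

test_that("k = n - 1 yields the complete graph and coincident points weight 1", {
  set.seed(21)
  e <- matrix(rnorm(12), 6, 2)
  g <- build_knn_graph(e, k = 5L)
  expect_true(all(g$W[upper.tri(g$W)] > 0))
  expect_true(all(diag(g$W) == 0))
  e2 <- rbind(c(1, 1), c(1, 1), c(5, 5))
  g2 <- build_knn_graph(e2, k = 1L)
  expect_equal(g2$W[1, 2], 1)
  expect_error(build_knn_graph(e2, k = 3L), class = "scdgi_validation_error")
})

test_that("KNN graph equals the brute-force all-pairs oracle on random points", {
  for (s in 1:3) {
    set.seed(s)
    n <- sample(10:50, 1)
    e <- matrix(rnorm(n * 3), n, 3)
    k <- sample(1:(n - 1), 1)
    expect_equal(build_knn_graph(e, k)$W, knn_oracle(e, k), tolerance = 1e-12)
  }
})

# hand-built graph: complete graph of uniform short edges plus one
# extreme edge between nodes that both have many short alternatives
extreme_edge_graph <- function() {
  n <- 11L
  D <- matrix(1, n, n)
  diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 10  # the extreme edge
  W <- 1 / (1 + D)
  diag(W) <- 0
  structure(list(n = n, W = W, D = D, L0 = NULL, k = n - 1L),
            class = "cell_graph")
}

test_that("pruning removes the extreme edge but keeps every node connected", {
  g <- extreme_edge_graph()
  p <- prune_graph(g, quantile = 0.9)
  expect_identical(p$L0[1, 2], 0)            # extreme edge gone
  expect_true(all(rowSums(p$L0) >= 1))       # connectivity floor
  expect_true(all(p$L0[p$L0 > 0] == 1))
  expect_true(all((p$L0 > 0) <= (p$W > 0)))  # L0 pattern within W pattern
  # quantile -> 1 limit removes nothing
  q1 <- prune_graph(g, quantile = 0.999)
  expect_equal(q1$L0, (g$W > 0) * 1, ignore_attr = TRUE)
})

test_that("pruning is idempotent and a star graph keeps its leaves attached", {
  g <- extreme_edge_graph()
  p1 <- prune_graph(g, quantile = 0.7)
  p2 <- prune_graph(p1, quantile = 0.7)
  expect_identical(p1$L0, p2$L0)
  # star: center 1 at origin, leaves at growing distances
  e <- rbind(c(0, 0), c(1, 0), c(0, 2), c(-4, 0), c(0, -8))
  gs <- prune_graph(build_knn_graph(e, k = 1L), quantile = 0.1)
  expect_true(all(rowSums(gs$L0) >= 1))
})

test_that("adjacency refinement obeys its endpoints and the hand-computed blend", {
  A <- matrix(c(0, 3, 1, 0), 2, 2, byrow = TRUE)
  L0 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(iterate_adjacency(A, L0, mu = 1), (L0 + t(L0)) / 2)
  expect_equal(iterate_adjacency(matrix(c(0, 2, 2, 0), 2, 2), L0, mu = 0,
                                 symmetrize = FALSE),
               matrix(c(0, 1, 1, 0), 2, 2))
  # mu = 0.5 hand oracle: row-normalized A is [[0,1],[1,0]]
  expect_equal(iterate_adjacency(A, L0, mu = 0.5, symmetrize = FALSE),
               matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))
})

test_that("refinement handles zero rows and satisfies the row-sum law", {
  A <- rbind(c(0, 2, 1), c(0, 0, 0), c(4, 0, 0))
  L0 <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  out <- iterate_adjacency(A, L0, mu = 0.3, symmetrize = FALSE)
  expect_true(all(is.finite(out)))
  expect_equal(out[2, ], c(0, 0, 0))
  # rows with nonzero sum: pre-symmetrization row sum = mu*L0sum + (1-mu)
  for (i in c(1, 3)) {
    expect_equal(sum(out[i, ]), 0.3 * sum(L0[i, ]) + 0.7)
  }
  expect_error(iterate_adjacency(-A, L0), class = "scdgi_validation_error")
})

test_that("graphs_equal is a max-norm comparison", {
  A <- matrix(runif(9), 3, 3)
  expect_true(graphs_equal(A, A, tol = 0))
  B <- A; B[2, 3] <- B[2, 3] + 1e-3 * 1.01
  expect_false(graphs_equal(A, B, tol = 1e-3))
  expect_true(graphs_equal(A, B, tol = Inf))
  expect_error(graphs_equal(A, matrix(0, 2, 2)), class = "scdgi_validation_error")
})
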