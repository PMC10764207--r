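# Imputation and clustering metrics against closed forms and
# independent oracles.

test_that("imputation metrics recover their closed forms", {
  x <- toy_matrix(rbind(c(1, 2, 0), c(0, 3, 4)))
  dr <- simulate_dropout(x, rate = 0.5, seed = 1L)
  # identity: perfect scores
  m <- imputation_metrics(x, x, dr$mask)
  expect_equal(m$median_l1, 0)
  expect_equal(m$mean_l1, 0)
  expect_equal(m$cosine, 1)
  expect_equal(m$rmse, 0)
})

test_that("orthogonal and hand-computed masked vectors give known values", {
  # construct a mask over two entries and control the value vectors
  x <- toy_matrix(rbind(c(1, 0), c(0, 5)))
  mask <- data.frame(cell = c(1L, 2L), gene = c(1L, 2L), value = c(1, 0))
  attr(mask, "rate") <- 0.5; attr(mask, "seed") <- 1L
  class(mask) <- c("dropout_mask", class(mask))
  # X = (1, 0) at masked entries, Y = (0, 1): orthogonal
  y <- toy_matrix(rbind(c(0, 9), c(9, 1)))
  xm <- toy_matrix(rbind(c(1, 9), c(9, 0)))
  expect_equal(imputation_metrics(xm, y, mask)$cosine, 0)
  # X = (0, 0), Y = (3, 4): RMSE = sqrt(25/2), median L1 = 3.5
  x0 <- toy_matrix(matrix(1e-9 + 0 * diag(2), 2, 2))
  x0[1, 1] <- 0; x0[2, 2] <- 0
  y2 <- toy_matrix(rbind(c(3, 0), c(0, 4)))
  m2 <- imputation_metrics(x0, y2, mask)
  expect_equal(m2$rmse, sqrt(12.5))
  expect_equal(m2$median_l1, 3.5)
  expect_equal(m2$mean_l1, 3.5)
})

test_that("metrics depend only on masked entries", {
  set.seed(61)
  x <- toy_matrix(matrix(runif(40, 1, 3), 5, 8))
  dr <- simulate_dropout(x, rate = 0.25, seed = 2L)
  y1 <- unclass(x) * 0.8
  y2 <- y1
  unmasked <- setdiff(seq_along(y2), (dr$mask$gene - 1L) * 5L + dr$mask$cell)
  y2[unmasked] <- 99
  m1 <- imputation_metrics(x, toy_matrix(y1), dr$mask)
  m2 <- imputation_metrics(x, toy_matrix(y2), dr$mask)
  expect_identical(m1, m2)
})

test_that("ARI matches hand-derived values and the mclust implementation", {
  expect_equal(ari(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  expect_equal(ari(c(0, 0, 1, 1), c(7, 7, 3, 3)), 1)  # relabel invariance
  skip_if_not_installed("mclust")
  set.seed(62)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    x <- sample(1:3, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    expect_equal(ari(x, y), mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
})

test_that("the mutual-information family matches loop oracles and igraph", {
  set.seed(63)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    x <- sample(1:3, n, replace = TRUE)
    y <- sample(1:3, n, replace = TRUE)
    o <- mi_oracle(x, y)
    m <- mutual_info_family(x, y)
    expect_equal(m$mi, max(o$mi, 0), tolerance = 1e-12)
    expect_equal(m$h_x, o$hx, tolerance = 1e-12)
    expect_equal(m$h_y, o$hy, tolerance = 1e-12)
    if ((o$hx + o$hy) > 0) {
      expect_equal(m$nmi, o$mi / ((o$hx + o$hy) / 2), tolerance = 1e-10)
    }
    # igraph cross-check for NMI (skip degenerate single-cluster draws)
    if (m$h_x > 0 && m$h_y > 0) {
      expect_equal(m$nmi, igraph::compare(x, y, method = "nmi"), tolerance = 1e-10)
    }
  }
})

test_that("AMI equals the exact permutation-model adjustment", {
  set.seed(64)
  for (i in 1:10) {
    n <- 6L
    x <- sample(1:3, n, replace = TRUE)
    y <- sample(1:3, n, replace = TRUE)
    expect_equal(mutual_info_family(x, y)$ami, ami_perm_oracle(x, y),
                 tolerance = 1e-10)
  }
})

test_that("degenerate partitions follow the stated conventions", {
  m <- mutual_info_family(rep(1, 5), rep(2, 5))  # both single-cluster
  expect_equal(unlist(m[c("nmi", "ami", "hs", "cs", "vms")]),
               c(nmi = 1, ami = 1, hs = 1, cs = 1, vms = 1))
  m2 <- mutual_info_family(rep(1, 4), c(1, 2, 1, 2))  # reference constant
  expect_equal(m2$mi, 0)
  expect_equal(m2$hs, 1)
  expect_equal(m2$nmi, 0)
  # identical nontrivial labelings, including a pure rotation
  m3 <- mutual_info_family(c(0, 0, 1, 1), c(1, 1, 0, 0))
  expect_equal(m3$mi, log(2))
  expect_equal(m3$nmi, 1)
  expect_equal(m3$ami, 1)
  expect_equal(m3$vms, 1)
})

test_that("metric symmetries hold", {
  set.seed(65)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    x <- sample(1:3, n, replace = TRUE)
    y <- sample(1:3, n, replace = TRUE)
    mxy <- mutual_info_family(x, y)
    myx <- mutual_info_family(y, x)
    expect_equal(mxy$mi, myx$mi, tolerance = 1e-12)
    expect_equal(mxy$nmi, myx$nmi, tolerance = 1e-12)
    expect_equal(mxy$ami, myx$ami, tolerance = 1e-10)
    expect_equal(mxy$hs, myx$cs, tolerance = 1e-12)  # HS(x,y) = CS(y,x)
    expect_equal(fms(x, y), fms(y, x), tolerance = 1e-12)
    expect_equal(ari(x, y), ari(y, x), tolerance = 1e-12)
  }
})

test_that("FMS matches the pair-enumeration oracle and its edge cases", {
  expect_equal(fms(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(fms(1:4, rep(1, 4)), 0)          # no co-clustered pair in x
  expect_equal(fms(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)  # TP = 0
  set.seed(66)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    x <- sample(1:3, n, replace = TRUE)
    y <- sample(1:3, n, replace = TRUE)
    expect_equal(fms(x, y), fms_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("the bundled report has the declared schema and perfect self-scores", {
  sim <- simulate_cells(40, 30, 2, seed = 3)
  xp <- log_normalize(sim$counts)
  dr <- simulate_dropout(xp, 0.1, seed = 4L)
  rep <- evaluation_report(xp, xp, dr$mask, sim$labels, sim$labels)
  expect_named(rep$imputation, c("median_l1", "mean_l1", "cosine", "rmse"))
  expect_named(rep$clustering, c("ari", "ami", "nmi", "hs", "cs", "vms", "fms"))
  expect_equal(unname(unlist(rep$clustering)), rep(1, 7))
  expect_equal(rep$imputation$rmse, 0)
  expect_equal(rep$metadata$dropout_rate, 0.1)
})
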