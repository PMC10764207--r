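# Evaluation metrics. Imputation metrics are computed over the masked
# entries of a simulated-dropout experiment; clustering metrics are the
# standard chance-adjusted / information-theoretic partition-agreement
# scores. All are implemented from their definitions (natural log
# throughout) and validated in the tests against exhaustive pair and
# contingency oracles.

#' Imputation metrics over masked entries
#'
#' Median and mean L1 distance, cosine similarity and RMSE between the
#' true and imputed values at exactly the masked positions.
#'
#' @param x_true matrix holding the ground-truth values.
#' @param y_imputed imputed matrix of the same shape.
#' @param mask `dropout_mask` from [simulate_dropout()].
#' @return list `median_l1`, `mean_l1`, `cosine`, `rmse`.
#' @export
imputation_metrics <- function(x_true, y_imputed, mask) {
  if (!all(dim(x_true) == dim(y_imputed))) stop_validation("shape mismatch")
  if (!inherits(mask, "dropout_mask") || nrow(mask) == 0L) {
    stop_validation("mask must be a nonempty dropout_mask")
  }
  xv <- masked_values(x_true, mask)
  yv <- masked_values(y_imputed, mask)
  d <- abs(xv - yv)
  nx <- sqrt(sum(xv^2)); ny <- sqrt(sum(yv^2))
  cosine <- if (nx == 0 || ny == 0) 0 else sum(xv * yv) / (nx * ny)
  list(median_l1 = median(d), mean_l1 = mean(d),
       cosine = cosine, rmse = sqrt(mean((xv - yv)^2)))
}

.contingency <- function(x, y) {
  if (length(x) != length(y)) stop_validation("label vectors differ in length")
  table(factor(x), factor(y))
}

#' Adjusted Rand Index
#'
#' Chance-adjusted pair-counting agreement between two partitions, via
#' the standard contingency-table form; 1 for identical partitions, 0 in
#' expectation for independent ones.
#'
#' @param x,y label vectors of equal length (>= 2).
#' @return numeric scalar.
#' @export
ari <- function(x, y) {
  if (length(x) < 2L) stop_validation("need at least 2 elements")
  ct <- .contingency(x, y)
  n <- length(x)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  tot <- choose(n, 2)
  expected <- sum_a * sum_b / tot
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions degenerate
  (sum_ij - expected) / (max_idx - expected)
}

.entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# exact expected mutual information under the permutation (hypergeometric)
# model with fixed marginals
.expected_mi <- function(a, b, n) {
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1L, ai + bj - n)
      hi <- min(ai, bj)
      if (lo > hi) next
      nij <- lo:hi
      lp <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) +
        lgamma(n - bj + 1) - lgamma(n + 1) - lgamma(nij + 1) -
        lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
        lgamma(n - ai - bj + nij + 1)
      emi <- emi + sum((nij / n) * log(n * nij / (ai * bj)) * exp(lp))
    }
  }
  emi
}

#' Mutual-information family of clustering metrics
#'
#' Computes, from the empirical joint distribution of two labelings
#' (natural log): mutual information `mi`, entropies `h_x`, `h_y`,
#' `nmi = mi / mean(h_x, h_y)`, `ami` (adjusted with the exact
#' permutation-model expected MI), homogeneity `hs = 1 - H(x|y)/H(x)`
#' (x is the reference partition), completeness `cs = 1 - H(y|x)/H(y)`
#' and the V-measure `vms = 2 hs cs / (hs + cs)`.
#'
#' Degenerate conventions: when both partitions are single-cluster the
#' normalized scores are all 1 (perfect agreement); when only the
#' reference (resp. predicted) partition is single-cluster, `hs` (resp.
#' `cs`) is 1 because the conditional entropy in its numerator is 0
#' along with its denominator; `nmi`/`ami` are 0 when their denominators
#' vanish with a nonzero entropy present.
#'
#' @param x reference labels.
#' @param y predicted labels, same length.
#' @return list `mi`, `h_x`, `h_y`, `nmi`, `ami`, `hs`, `cs`, `vms`.
#' @export
mutual_info_family <- function(x, y) {
  ct <- .contingency(x, y)
  n <- sum(ct)
  a <- rowSums(ct); b <- colSums(ct)
  h_x <- .entropy(a); h_y <- .entropy(b)
  p <- ct / n
  nz <- which(p > 0)
  px <- (a / n)[row(ct)[nz]]; py <- (b / n)[col(ct)[nz]]
  mi <- sum(p[nz] * log(p[nz] / (px * py)))
  mi <- max(mi, 0)  # clip tiny negative rounding

  if (h_x == 0 && h_y == 0) {
    return(list(mi = 0, h_x = 0, h_y = 0, nmi = 1, ami = 1,
                hs = 1, cs = 1, vms = 1))
  }
  mean_h <- (h_x + h_y) / 2
  nmi <- if (mean_h > 0) mi / mean_h else 0
  emi <- .expected_mi(a, b, n)
  denom <- mean_h - emi
  ami <- if (abs(denom) < 1e-12) 0 else (mi - emi) / denom

  # conditional entropies from the joint
  h_x_given_y <- h_x - mi + 0  # identity H(x|y) = H(x) - MI
  h_y_given_x <- h_y - mi
  hs <- if (h_x == 0) 1 else 1 - max(h_x_given_y, 0) / h_x
  cs <- if (h_y == 0) 1 else 1 - max(h_y_given_x, 0) / h_y
  vms <- if (hs + cs == 0) 0 else 2 * hs * cs / (hs + cs)
  list(mi = mi, h_x = h_x, h_y = h_y, nmi = nmi, ami = ami,
       hs = hs, cs = cs, vms = vms)
}

#' Fowlkes–Mallows score
#'
#' Geometric mean of pairwise precision and recall:
#' `TP / sqrt((TP + FP) * (TP + FN))`, where TP counts element pairs
#' co-clustered in both partitions, FP pairs co-clustered only in `x`,
#' FN only in `y`. Returns 0 when either partition has no co-clustered
#' pair.
#'
#' @param x,y label vectors of equal length (>= 2).
#' @return numeric in \[0, 1\].
#' @export
fms <- function(x, y) {
  if (length(x) < 2L) stop_validation("need at least 2 elements")
  ct <- .contingency(x, y)
  tp <- sum(choose(ct, 2))
  tp_fp <- sum(choose(rowSums(ct), 2))
  tp_fn <- sum(choose(colSums(ct), 2))
  if (tp_fp == 0 || tp_fn == 0) return(0)
  tp / sqrt(tp_fp * tp_fn)
}

#' All seven clustering metrics at once
#'
#' @param truth reference labels.
#' @param pred predicted labels.
#' @return list `ari`, `ami`, `nmi`, `hs`, `cs`, `vms`, `fms`.
#' @export
clustering_metrics <- function(truth, pred) {
  mif <- mutual_info_family(truth, pred)
  list(ari = ari(truth, pred), ami = mif$ami, nmi = mif$nmi,
       hs = mif$hs, cs = mif$cs, vms = mif$vms, fms = fms(truth, pred))
}

#' Full evaluation report
#'
#' Bundles the four imputation metrics (computed at the masked entries)
#' and the seven clustering metrics into one report, mirroring the
#' package's evaluation protocol.
#'
#' @param x_true,y_imputed,mask see [imputation_metrics()]; all three
#'   `NULL` to skip the imputation block.
#' @param truth,pred see [clustering_metrics()]; both `NULL` to skip the
#'   clustering block.
#' @return list with elements `imputation`, `clustering`, `metadata`.
#' @export
evaluation_report <- function(x_true = NULL, y_imputed = NULL, mask = NULL,
                              truth = NULL, pred = NULL) {
  imp <- if (!is.null(x_true)) imputation_metrics(x_true, y_imputed, mask) else NULL
  clu <- if (!is.null(truth)) clustering_metrics(truth, pred) else NULL
  meta <- list(
    dropout_rate = if (!is.null(mask)) attr(mask, "rate") else NA_real_,
    seed = if (!is.null(mask)) attr(mask, "seed") else NA_integer_,
    n_masked = if (!is.null(mask)) nrow(mask) else NA_integer_
  )
  list(imputation = imp, clustering = clu, metadata = meta)
}
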