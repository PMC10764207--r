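# Left-truncated mixture Gaussian (LTMG) discretization.
#
# Each gene's expression across cells is modelled as a K-component
# Gaussian mixture in which values at or below a truncation point `zcut`
# are left-censored: they contribute the component CDF mass below `zcut`
# to the likelihood instead of a density. On log-normalized data the
# censored mass is exactly the dropout zeros. EM handles the censoring
# through truncated-normal sufficient statistics, BIC picks K, and each
# value is then assigned its most probable component — its
# transcriptional regulatory state (TRS).

# truncated-normal moments for X ~ N(mu, sigma^2) conditioned on X <= t
.trunc_moments <- function(mu, sigma, t) {
  beta <- (t - mu) / sigma
  lphi <- dnorm(beta, log = TRUE) - pnorm(beta, log.p = TRUE)
  m <- exp(lphi)                     # phi(beta)/Phi(beta), stable for beta << 0
  m[!is.finite(m)] <- -beta[!is.finite(m)]
  e1 <- mu - sigma * m
  v <- sigma^2 * pmax(1 - beta * m - m^2, 0)
  list(m1 = e1, m2 = v + e1^2)
}

.ltmg_em <- function(obs, n_cens, K, zcut, max_iter, tol, sigma_floor) {
  n <- length(obs) + n_cens
  # deterministic init: quantile-spaced means over observed values
  mu <- as.numeric(quantile(obs, probs = (seq_len(K) - 0.5) / K, names = FALSE))
  sg <- rep(max(sd(obs) / K, sigma_floor), K)
  if (!is.finite(sg[1L])) sg <- rep(sigma_floor, K)
  al <- rep(1 / K, K)
  loglik <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k) al[k] * dnorm(obs, mu[k], sg[k]),
                   numeric(length(obs)))
    dens <- matrix(dens, nrow = length(obs))
    rs <- rowSums(dens)
    ll_obs <- sum(log(pmax(rs, 1e-300)))
    if (n_cens > 0L) {
      cmass <- al * pnorm(zcut, mu, sg)
      ll_cens <- n_cens * log(max(sum(cmass), 1e-300))
    } else {
      cmass <- rep(0, K)
      ll_cens <- 0
    }
    ll <- ll_obs + ll_cens
    trace <- c(trace, ll)
    if (is.finite(loglik) && abs(ll - loglik) < tol) {
      loglik <- ll
      break
    }
    loglik <- ll

    r_obs <- dens / pmax(rs, 1e-300)
    r_obs[rs <= 0, ] <- 1 / K
    if (n_cens > 0L) {
      r_cens <- if (sum(cmass) > 0) cmass / sum(cmass) else rep(1 / K, K)
      tm <- .trunc_moments(mu, sg, zcut)
    } else {
      r_cens <- rep(0, K)
      tm <- list(m1 = rep(0, K), m2 = rep(0, K))
    }
    Nk <- colSums(r_obs) + n_cens * r_cens
    if (any(Nk < 1e-8)) return(NULL)  # empty component: reject this K
    al <- Nk / n
    mu_new <- (colSums(r_obs * obs) + n_cens * r_cens * tm$m1) / Nk
    ss <- colSums(r_obs * (outer(obs, mu_new, "-")^2)) +
      n_cens * r_cens * (tm$m2 - 2 * mu_new * tm$m1 + mu_new^2)
    sg <- pmax(sqrt(pmax(ss / Nk, 0)), sigma_floor)
    mu <- mu_new
  }
  list(alphas = al, mus = mu, sigmas = sg, loglik = loglik,
       n_params = 3 * K - 1, trace = trace)
}

#' Fit the LTMG model to one gene
#'
#' Runs left-censored mixture EM for each K in `1:k_max` and returns the
#' fit minimizing BIC (`-2 logLik + p log n`, `p = 3K - 1`). Values at or
#' below `zcut` are treated as left-censored. The fit is deterministic:
#' EM is initialized from quantile-spaced means.
#'
#' @param x numeric expression vector across cells (length >= 2).
#' @param zcut left-truncation threshold; with log-normalized input the
#'   default 0 makes the zeros the censored mass.
#' @param k_max largest number of mixture components to consider.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param sigma_floor lower bound on component standard deviations.
#' @param seed accepted for interface symmetry; the fit has no random
#'   element.
#' @return an object of class `ltmg_fit`: list with `K`, `alphas`, `mus`,
#'   `sigmas`, `zcut`, `loglik`, `bic`, `censored_only`, `loglik_trace`.
#' @export
ltmg_fit_gene <- function(x, zcut = 0, k_max = 5L, max_iter = 200L,
                          tol = 1e-6, sigma_floor = 1e-3, seed = NULL) {
  if (!is.numeric(x) || length(x) < 2L) stop_validation("need >= 2 expression values")
  if (anyNA(x) || any(!is.finite(x))) stop_validation("non-finite expression values")
  obs <- x[x > zcut]
  n_cens <- length(x) - length(obs)

  if (length(obs) == 0L) {
    fit <- list(K = 1L, alphas = 1, mus = zcut, sigmas = sigma_floor,
                zcut = zcut, loglik = length(x) * log(0.5), bic = NA_real_,
                censored_only = TRUE, loglik_trace = numeric(0))
    class(fit) <- "ltmg_fit"
    return(fit)
  }

  k_cap <- min(as.integer(k_max), length(unique(obs)))
  best <- NULL
  best_bic <- Inf
  for (K in seq_len(max(k_cap, 1L))) {
    em <- .ltmg_em(obs, n_cens, K, zcut, max_iter, tol, sigma_floor)
    if (is.null(em)) next
    bic <- -2 * em$loglik + em$n_params * log(length(x))
    if (bic < best_bic - 1e-12) {
      best_bic <- bic
      best <- c(em, list(K = K, bic = bic))
    }
  }
  if (is.null(best)) {
    best <- list(alphas = 1, mus = mean(obs), sigmas = max(sd(obs), sigma_floor),
                 loglik = NA_real_, K = 1L, bic = NA_real_, trace = numeric(0))
  }
  fit <- list(K = best$K, alphas = best$alphas, mus = best$mus,
              sigmas = best$sigmas, zcut = zcut, loglik = best$loglik,
              bic = best$bic, censored_only = FALSE,
              loglik_trace = best$trace)
  class(fit) <- "ltmg_fit"
  fit
}

#' Assign each expression value to its regulatory state
#'
#' Each value is labelled with the mixture component maximizing
#' `alpha_i * dnorm(x, mu_i, sigma_i)`; ties go to the lowest component
#' index. Components are ordered by increasing mean so state 1 is the
#' lowest-expression regime.
#'
#' @param x numeric expression vector.
#' @param fit an `ltmg_fit`.
#' @return integer vector of states in `1:fit$K`.
#' @export
ltmg_discretize <- function(x, fit) {
  if (!inherits(fit, "ltmg_fit")) stop_validation("fit must be an ltmg_fit")
  ord <- order(fit$mus)
  al <- fit$alphas[ord]; mu <- fit$mus[ord]; sg <- fit$sigmas[ord]
  K <- fit$K
  if (K == 1L) return(rep(1L, length(x)))
  scores <- vapply(seq_len(K), function(k) al[k] * dnorm(x, mu[k], sg[k]),
                   numeric(length(x)))
  scores <- matrix(scores, nrow = length(x))
  max.col(scores, ties.method = "first")
}

#' Fit LTMG to every gene of an expression matrix
#'
#' Independent per-gene fits via [ltmg_fit_gene()]; a gene whose fit
#' fails falls back to a single-component fit (and is recorded in
#' `failed`). The discrete TRS matrix is assembled column-wise.
#'
#' @param x cells-by-genes expression matrix (normally log-normalized).
#' @inheritParams ltmg_fit_gene
#' @param verbose log per-gene progress every 200 genes.
#' @return object of class `ltmg_matrix_fit`: list with `fits` (per-gene
#'   `ltmg_fit`s), `trs` (integer cells-by-genes state matrix), `k`
#'   (per-gene K) and `failed` (character vector of gene ids).
#' @export
ltmg_fit <- function(x, zcut = 0, k_max = 5L, max_iter = 200L, tol = 1e-6,
                     sigma_floor = 1e-3, seed = NULL, verbose = FALSE) {
  validate_expression_matrix(x)
  p <- ncol(x)
  fits <- vector("list", p)
  trs <- matrix(1L, nrow(x), p, dimnames = dimnames(x))
  failed <- character(0)
  for (j in seq_len(p)) {
    fit <- tryCatch(
      ltmg_fit_gene(x[, j], zcut = zcut, k_max = k_max, max_iter = max_iter,
                    tol = tol, sigma_floor = sigma_floor),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      failed <- c(failed, colnames(x)[j])
      fit <- list(K = 1L, alphas = 1, mus = mean(x[, j]),
                  sigmas = max(sd(x[, j]), sigma_floor), zcut = zcut,
                  loglik = NA_real_, bic = NA_real_, censored_only = FALSE,
                  loglik_trace = numeric(0))
      class(fit) <- "ltmg_fit"
    }
    fits[[j]] <- fit
    trs[, j] <- ltmg_discretize(x[, j], fit)
    if (verbose && j %% 200L == 0L) scdgi_log(verbose, "LTMG: %d/%d genes", j, p)
  }
  out <- list(fits = fits, trs = trs,
              k = vapply(fits, function(f) f$K, integer(1)),
              failed = failed)
  class(out) <- "ltmg_matrix_fit"
  out
}

#' Rescale TRS states to loss weights
#'
#' Maps each gene's discrete states 1..K to weights in \[0, 1\] via
#' `(state - 1) / (K - 1)`; genes with K = 1 get weight 1 everywhere.
#' Used to weight squared reconstruction residuals in the imputation
#' loss so that high-state (actively regulated) values count more.
#'
#' @param ltmg an `ltmg_matrix_fit`.
#' @return numeric cells-by-genes weight matrix.
#' @export
trs_weights <- function(ltmg) {
  if (!inherits(ltmg, "ltmg_matrix_fit")) stop_validation("need an ltmg_matrix_fit")
  w <- matrix(1, nrow(ltmg$trs), ncol(ltmg$trs), dimnames = dimnames(ltmg$trs))
  for (j in seq_len(ncol(w))) {
    K <- ltmg$k[j]
    w[, j] <- if (K == 1L) 1 else (ltmg$trs[, j] - 1) / (K - 1)
  }
  w
}

#' @export
print.ltmg_fit <- function(x, ...) {
  cat(sprintf("LTMG fit: K = %d, BIC = %s\n", x$K, format(x$bic)))
  cat("  alpha:", signif(x$alphas, 4), "\n")
  cat("  mu:   ", signif(x$mus, 4), "\n")
  cat("  sigma:", signif(x$sigmas, 4), "\n")
  invisible(x)
}
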