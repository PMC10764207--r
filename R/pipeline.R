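# The full model fit: preprocessing -> LTMG -> [feature AE -> MLP ->
# cell graph -> VGAE -> Louvain/k-means -> cluster AEs -> adjacency
# refinement]* until the graph or the labels stabilize -> imputation AE
# on the original preprocessed matrix.

#' Configuration for a scdgi fit
#'
#' Returns the default configuration; any block can be overridden by
#' passing a named list that is merged over the defaults, e.g.
#' `scdgi_config(vgae = list(n_heads = 0), max_outer_iterations = 2)`.
#'
#' Blocks and notable defaults: `preprocess` (top 2000 variable genes,
#' log1p), `ltmg` (zcut 0, up to 5 components), `feature_ae`
#' (p -> 512 -> 128 mirrored, 500 epochs), `mlp` (64/32/16 Tanh,
#' trained-refiner mode), `graph` (adaptive k = max(5, sqrt(n)), prune
#' quantile 0.9, blend mu 0.5), `vgae` (dims 32/16, 3 heads, lr 0.001),
#' `clustering` (Louvain resolution 1, ARI convergence 0.99, graph
#' tolerance 1e-4), `cluster_ae`, `imputation` (alpha = beta = 0.5,
#' gamma1 = gamma2 = 0.1), `max_outer_iterations` (10) and `seed`.
#'
#' @param ... named blocks or scalars overriding the defaults.
#' @return nested list of class `scdgi_config`.
#' @export
scdgi_config <- function(...) {
  cfg <- list(
    preprocess = list(n_top = 2000L, min_cells = 1L, min_genes = 1L,
                      log_transform = TRUE),
    ltmg = list(zcut = 0, k_max = 5L, max_iter = 200L, tol = 1e-6,
                sigma_floor = 1e-3),
    feature_ae = list(hidden = c(512L, 128L), epochs = 500L, lr = 1e-3,
                      trs_weighting = FALSE),
    mlp = list(hidden = c(64L, 32L, 16L), mode = "trained", epochs = 200L,
               lr = 1e-3),
    graph = list(k = NULL, prune_quantile = 0.9, mu = 0.5),
    vgae = list(enabled = TRUE, dims = c(32L, 16L), n_heads = 3L,
                epochs = 200L, lr = 1e-3, kl_weight = NULL),
    clustering = list(resolution = 1, ari_threshold = 0.99,
                      graph_tol = 1e-4),
    cluster_ae = list(hidden = c(128L, 64L), epochs = 200L, lr = 1e-3),
    imputation = list(alpha = 0.5, beta = 0.5, gamma1 = 0.1, gamma2 = 0.1,
                      hidden = c(128L, 64L), epochs = 500L, lr = 1e-3),
    max_outer_iterations = 10L,
    seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]] <- modifyList(cfg[[nm]], over[[nm]])
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = c("scdgi_config", "list"))
}

#' Fit the deep graph imputation and clustering model
#'
#' Runs the full pipeline on a cells-by-genes expression matrix: quality
#' filtering, variable-gene selection and log-normalization; per-gene
#' LTMG discretization; then an outer refinement loop (feature
#' auto-encoder, Tanh MLP encoder, pruned KNN cell graph, variational
#' graph auto-encoder, Louvain cluster count + k-means assignment,
#' per-cluster auto-encoders rebuilding the matrix, convex adjacency
#' update) until the refined adjacency or the labels stabilize; and
#' finally the regularized imputation auto-encoder on the original
#' preprocessed matrix. On convergence the previous iteration's labels
#' are kept as the final clustering.
#'
#' @param x cells-by-genes nonnegative expression matrix (counts or
#'   normalized values) with cell and gene ids.
#' @param config a [scdgi_config()].
#' @param impute train the final imputation auto-encoder (set `FALSE`
#'   for clustering-only runs).
#' @param verbose log per-stage progress and wall time.
#' @return object of class `scdgi`; see [print.scdgi()],
#'   [summary.scdgi()], [fitted.scdgi()], [residuals.scdgi()],
#'   [predict.scdgi()], [plot.scdgi()].
#' @export
scdgi <- function(x, config = scdgi_config(), impute = TRUE, verbose = FALSE) {
  cl <- match.call()
  validate_expression_matrix(x)
  cfg <- config
  seed <- as.integer(cfg$seed)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(fmt, ...) {
    scdgi_log(verbose, paste0("[%.1fs] ", fmt),
              proc.time()[["elapsed"]] - t0, ...)
  }

  # ---- preprocessing -------------------------------------------------
  xp <- filter_matrix(x, min_cells = cfg$preprocess$min_cells,
                      min_genes = cfg$preprocess$min_genes)
  xp <- select_top_genes(xp, cfg$preprocess$n_top)
  if (cfg$preprocess$log_transform && !isTRUE(attr(xp, "log_transformed"))) {
    xp <- log_normalize(xp)
  }
  n <- nrow(xp)
  stage("preprocessed: %d cells x %d genes", n, ncol(xp))

  # ---- LTMG ----------------------------------------------------------
  need_trs <- (impute && cfg$imputation$alpha > 0) ||
    isTRUE(cfg$feature_ae$trs_weighting)
  ltmg <- NULL
  trs_w <- NULL
  if (need_trs) {
    ltmg <- ltmg_fit(xp, zcut = cfg$ltmg$zcut, k_max = cfg$ltmg$k_max,
                     max_iter = cfg$ltmg$max_iter, tol = cfg$ltmg$tol,
                     sigma_floor = cfg$ltmg$sigma_floor, verbose = verbose)
    trs_w <- trs_weights(ltmg)
    stage("LTMG: %d genes, K distribution: %s", ncol(xp),
          paste(names(table(ltmg$k)), table(ltmg$k), sep = ":", collapse = " "))
  }

  # ---- outer refinement loop ----------------------------------------
  k_graph <- if (is.null(cfg$graph$k)) max(5L, round(sqrt(n))) else cfg$graph$k
  x_iter <- xp
  prev_labels <- NULL
  prev_A <- NULL
  final_labels <- NULL
  history <- list()
  converged <- FALSE
  graph <- NULL
  A_ref <- NULL
  embedding <- NULL
  n_clusters <- NA_integer_

  for (t in seq_len(cfg$max_outer_iterations)) {
    s_t <- seed + 100L * t
    fae <- train_feature_ae(x_iter, hidden = cfg$feature_ae$hidden,
                            epochs = cfg$feature_ae$epochs,
                            lr = cfg$feature_ae$lr, seed = s_t,
                            trs_w = if (isTRUE(cfg$feature_ae$trs_weighting)) trs_w else NULL)
    stage("iter %d: feature AE loss %.4g -> %.4g", t,
          fae$loss_trace[1L], fae$loss_trace[length(fae$loss_trace)])
    mlp <- train_mlp_encoder(fae$embedding, hidden = cfg$mlp$hidden,
                             mode = cfg$mlp$mode, epochs = cfg$mlp$epochs,
                             lr = cfg$mlp$lr, seed = s_t + 1L)
    graph <- build_knn_graph(mlp$embedding, k = k_graph)
    graph <- prune_graph(graph, quantile = cfg$graph$prune_quantile)
    stage("iter %d: graph %d edges, %d after pruning", t,
          sum(graph$W > 0) / 2, sum(graph$L0) / 2)

    # with the VGAE on, its denoised reconstructed adjacency carries the
    # cluster structure (dense within communities, so Louvain is not bitten
    # by the resolution limit) and feeds the refinement update; without it,
    # the pruned weighted KNN graph is used directly
    if (isTRUE(cfg$vgae$enabled)) {
      vg <- train_vgae(graph, mlp$embedding, dims = cfg$vgae$dims,
                       n_heads = cfg$vgae$n_heads, epochs = cfg$vgae$epochs,
                       lr = cfg$vgae$lr, seed = s_t + 2L,
                       kl_weight = cfg$vgae$kl_weight)
      embedding <- vg$embedding
      A_weighted <- vg$Ahat
      diag(A_weighted) <- 0
      stage("iter %d: VGAE loss %.4g -> %.4g", t, vg$loss_trace[1L],
            vg$loss_trace[length(vg$loss_trace)])
    } else {
      embedding <- mlp$embedding
      A_weighted <- graph$W * graph$L0
    }

    k_est <- louvain_k(A_weighted, resolution = cfg$clustering$resolution,
                       seed = s_t + 5L)
    k_est <- min(max(k_est, 1L), n)
    assign_t <- kmeans_cluster(embedding, k_est, seed = s_t + 3L)
    stage("iter %d: Louvain k = %d, k-means sizes: %s", t, k_est,
          paste(table(assign_t$labels), collapse = "/"))

    A_ref <- iterate_adjacency(A_weighted, graph$L0, mu = cfg$graph$mu)

    rec <- list(iteration = t, k = k_est, labels = assign_t$labels)
    if (t > 1L) {
      lab_ari <- ari(prev_labels, assign_t$labels)
      graph_same <- !is.null(prev_A) &&
        graphs_equal(prev_A, A_ref, tol = cfg$clustering$graph_tol)
      rec$ari_vs_prev <- lab_ari
      rec$graph_delta <- if (!is.null(prev_A)) max(abs(prev_A - A_ref)) else NA_real_
      if (graph_same || lab_ari >= cfg$clustering$ari_threshold) {
        converged <- TRUE
        final_labels <- prev_labels  # prior iteration's clustering is final
        n_clusters <- length(unique(prev_labels))
        history[[t]] <- rec
        stage("converged at iteration %d (ARI %.3f)", t, lab_ari)
        break
      }
    }
    history[[t]] <- rec
    prev_labels <- assign_t$labels
    prev_A <- A_ref

    if (t < cfg$max_outer_iterations) {
      rebuilt <- train_cluster_aes(fae$reconstruction, assign_t$labels,
                                   hidden = cfg$cluster_ae$hidden,
                                   epochs = cfg$cluster_ae$epochs,
                                   lr = cfg$cluster_ae$lr, seed = s_t + 4L,
                                   verbose = verbose)
      x_iter <- pmax(rebuilt, 0)
      attr(x_iter, "log_transformed") <- attr(xp, "log_transformed")
    }
  }
  if (!converged) {
    final_labels <- prev_labels
    n_clusters <- length(unique(prev_labels))
  }
  final_labels <- relabel_first_occurrence(final_labels)

  # ---- imputation ----------------------------------------------------
  imputed <- NULL
  imp_fit <- NULL
  if (impute) {
    imp_fit <- train_imputer(xp, trs_w = trs_w, A = A_ref,
                             labels = final_labels,
                             alpha = cfg$imputation$alpha,
                             beta = cfg$imputation$beta,
                             gamma1 = cfg$imputation$gamma1,
                             gamma2 = cfg$imputation$gamma2,
                             hidden = cfg$imputation$hidden,
                             epochs = cfg$imputation$epochs,
                             lr = cfg$imputation$lr, seed = seed + 99L)
    imputed <- imp_fit$imputed
    stage("imputation AE loss %.4g -> %.4g", imp_fit$loss_trace[1L],
          imp_fit$loss_trace[length(imp_fit$loss_trace)])
  }

  structure(list(
    call = cl,
    config = cfg,
    x_preprocessed = xp,
    ltmg = ltmg,
    labels = final_labels,
    n_clusters = n_clusters,
    embedding = embedding,
    graph = graph,
    adjacency = A_ref,
    imputed = imputed,
    imputation = imp_fit[c("loss_trace", "components")],
    history = history,
    iterations = length(history),
    converged = converged
  ), class = "scdgi")
}

#' @export
print.scdgi <- function(x, ...) {
  cat("scdgi fit\n")
  cat(sprintf("  cells: %d, genes retained: %d\n",
              nrow(x$x_preprocessed), ncol(x$x_preprocessed)))
  cat(sprintf("  clusters: %d (%s after %d outer iteration%s)\n",
              x$n_clusters,
              if (x$converged) "converged" else "iteration cap reached",
              x$iterations, if (x$iterations == 1L) "" else "s"))
  if (!is.null(x$imputed)) {
    zi <- mean(x$x_preprocessed == 0)
    zo <- mean(x$imputed == 0)
    cat(sprintf("  imputed: zero fraction %.3f -> %.3f\n", zi, zo))
  }
  invisible(x)
}

#' @export
summary.scdgi <- function(object, ...) {
  out <- list(
    n_cells = nrow(object$x_preprocessed),
    n_genes = ncol(object$x_preprocessed),
    n_clusters = object$n_clusters,
    cluster_sizes = table(object$labels),
    converged = object$converged,
    iterations = object$iterations,
    k_per_iteration = vapply(object$history, `[[`, integer(1), "k"),
    ltmg_k = if (!is.null(object$ltmg)) table(object$ltmg$k) else NULL,
    imputation_components = object$imputation$components
  )
  class(out) <- "summary.scdgi"
  out
}

#' @export
print.summary.scdgi <- function(x, ...) {
  cat(sprintf("scdgi fit: %d cells x %d genes, %d clusters (%s, %d iterations)\n",
              x$n_cells, x$n_genes, x$n_clusters,
              if (x$converged) "converged" else "cap reached", x$iterations))
  cat("cluster sizes:\n"); print(x$cluster_sizes)
  cat("Louvain k per iteration:", x$k_per_iteration, "\n")
  if (!is.null(x$ltmg_k)) { cat("LTMG components per gene:\n"); print(x$ltmg_k) }
  if (!is.null(x$imputation_components)) {
    ic <- x$imputation_components
    cat(sprintf("imputation loss: total %.4g (mse %.4g, trs %.4g, l1 %.4g, graph %.4g, cluster %.4g)\n",
                ic$total, ic$mse, ic$trs, ic$l1, ic$graph, ic$cluster))
  }
  invisible(x)
}

#' Extract the imputed expression matrix
#' @param object a `scdgi` fit.
#' @param ... unused.
#' @export
fitted.scdgi <- function(object, ...) {
  if (is.null(object$imputed)) stop_validation("fit was run with impute = FALSE")
  object$imputed
}

#' Reconstruction residuals (preprocessed minus imputed)
#' @param object a `scdgi` fit.
#' @param ... unused.
#' @export
residuals.scdgi <- function(object, ...) {
  object$x_preprocessed - fitted(object)
}

#' Extract fit results
#'
#' @param object a `scdgi` fit.
#' @param type `"imputed"` (default), `"labels"` or `"embedding"`.
#' @param ... unused.
#' @export
predict.scdgi <- function(object, type = c("imputed", "labels", "embedding"),
                          ...) {
  type <- match.arg(type)
  switch(type,
         imputed = fitted(object),
         labels = object$labels,
         embedding = object$embedding)
}

#' Plot the cell embedding coloured by cluster
#'
#' Projects the final embedding to its first two principal components
#' and colours cells by assigned cluster.
#'
#' @param x a `scdgi` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.scdgi <- function(x, ...) {
  pc <- prcomp(x$embedding, rank. = 2L)$x
  cols <- rainbow(max(x$labels))
  plot(pc[, 1L], pc[, 2L], col = cols[x$labels], pch = 19,
       xlab = "PC1", ylab = "PC2", main = "scdgi cell embedding", ...)
  legend("topright", legend = paste("cluster", seq_len(max(x$labels))),
         col = cols, pch = 19, cex = 0.8)
}
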