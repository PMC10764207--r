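# Seeded synthetic scRNA-seq generator. Emulates the structural features
# the pipeline relies on — cluster-structured counts, overdispersion,
# high sparsity with expression-dependent dropout — so every stage is
# testable without external data. The generative model (documented in
# the methods vignette) is: uniform cluster assignment; log-normal base
# gene means; disjoint per-cluster marker sets whose means are shifted
# up by `separation` natural-log units in their own cluster;
# negative-binomial counts; and logistic expression-dependent dropout
# (weakly expressed genes drop out more).

#' Generate a synthetic expression matrix with known structure
#'
#' @param n_cells,n_genes,n_clusters matrix dimensions and number of cell
#'   types (`n_clusters <= n_cells`).
#' @param separation mean natural-log fold change of marker genes in
#'   their own cluster; 0 gives a null dataset with no cluster signal.
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param dropout_logit_scale steepness `s` of the logistic dropout
#'   probability `plogis(s * (midpoint - log1p(mu)))`; `0` disables
#'   dropout. Larger `s` pushes weakly expressed genes toward certain
#'   dropout.
#' @param dropout_midpoint expression level (log1p of the mean) at which
#'   the dropout probability is 1/2.
#' @param marker_fraction fraction of genes used as cluster markers
#'   (split evenly and disjointly across clusters).
#' @param seed integer seed; output is fully deterministic given the
#'   spec.
#' @return list with `counts` (observed cells-by-genes matrix, after
#'   dropout), `truth` (pre-dropout matrix), `labels` (integer cluster
#'   per cell), `markers` (list of marker gene indices per cluster),
#'   `spec` (the generating parameters).
#' @export
simulate_cells <- function(n_cells = 300L, n_genes = 500L, n_clusters = 3L,
                           separation = 4, dispersion = 0.5,
                           dropout_logit_scale = 1, dropout_midpoint = 2,
                           marker_fraction = 0.1, seed = 1L) {
  if (n_cells < 1L || n_genes < 1L || n_clusters < 1L) {
    stop_validation("n_cells, n_genes, n_clusters must be positive")
  }
  if (n_clusters > n_cells) stop_validation("n_clusters cannot exceed n_cells")
  if (separation < 0) stop_validation("separation must be >= 0")
  spec <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
               n_clusters = as.integer(n_clusters), separation = separation,
               dispersion = dispersion,
               dropout_logit_scale = dropout_logit_scale,
               dropout_midpoint = dropout_midpoint,
               marker_fraction = marker_fraction, seed = as.integer(seed))
  set.seed(as.integer(seed))
  labels <- sample.int(n_clusters, n_cells, replace = TRUE)
  # make sure every cluster is populated
  labels[seq_len(n_clusters)] <- seq_len(n_clusters)

  base_mu <- rlnorm(n_genes, meanlog = 0.5, sdlog = 1)
  n_mark <- max(1L, floor(marker_fraction * n_genes / n_clusters))
  marker_pool <- sample.int(n_genes, n_mark * n_clusters)
  markers <- split(marker_pool, rep(seq_len(n_clusters), each = n_mark))

  # per-cluster expected expression programs
  mu_k <- matrix(rep(base_mu, each = n_clusters), n_clusters, n_genes)
  for (k in seq_len(n_clusters)) {
    mu_k[k, markers[[k]]] <- mu_k[k, markers[[k]]] * exp(separation)
  }

  mu_cells <- mu_k[labels, , drop = FALSE]
  size <- 1 / max(dispersion, 1e-8)
  truth <- matrix(rnbinom(n_cells * n_genes, mu = mu_cells, size = size),
                  n_cells, n_genes)
  counts <- truth
  if (dropout_logit_scale > 0) {
    p_drop <- plogis(dropout_logit_scale * (dropout_midpoint - log1p(mu_cells)))
    drop <- matrix(runif(n_cells * n_genes) < p_drop, n_cells, n_genes)
    counts[drop] <- 0L
  }
  ids <- list(cells = sprintf("cell_%03d", seq_len(n_cells)),
              genes = sprintf("gene_%04d", seq_len(n_genes)))
  dimnames(counts) <- dimnames(truth) <- list(ids$cells, ids$genes)
  attr(counts, "log_transformed") <- FALSE
  attr(truth, "log_transformed") <- FALSE
  list(counts = counts, truth = truth, labels = labels,
       markers = markers, spec = spec)
}

#' Write a synthetic dataset to disk as plain-text fixture files
#'
#' Writes the observed matrix as dense CSV and MatrixMarket (the MTX
#' carries `_genes.txt` / `_cells.txt` sidecars), the labels and the
#' pre-dropout truth matrix as CSV, and the generating spec as JSON, so
#' the dataset can be regenerated bit-identically.
#'
#' @param sim result of [simulate_cells()].
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    matrix_csv = file.path(dir, "matrix.csv"),
    matrix_mtx = file.path(dir, "matrix.mtx"),
    labels = file.path(dir, "labels.csv"),
    truth = file.path(dir, "truth.csv"),
    spec = file.path(dir, "spec.json")
  )
  write_matrix(sim$counts, files["matrix_csv"], format = "csv")
  write_matrix(sim$counts, files["matrix_mtx"], format = "mtx")
  write_labels(sim$labels, files["labels"], cell_ids = rownames(sim$counts))
  write_matrix(sim$truth, files["truth"], format = "csv")
  jsonlite::write_json(sim$spec, files["spec"], auto_unbox = TRUE, digits = NA)
  side <- mtx_sidecars(files[["matrix_mtx"]])
  invisible(c(unname(files), unname(side)))
}

#' Regenerate a synthetic dataset from a stored spec
#'
#' @param path `spec.json` written by [write_fixture()].
#' @return the [simulate_cells()] result for that spec.
#' @export
read_fixture_spec <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(simulate_cells, spec)
}
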