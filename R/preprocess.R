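# Preprocessing: quality filtering, variable-gene selection, log
# transformation and the dropout-simulation protocol used to score
# imputation.

#' Drop empty cells and rarely expressed genes
#'
#' Quality filter applied before gene selection: cells must have nonzero
#' counts in at least `min_genes` genes and genes must be expressed in at
#' least `min_cells` cells.
#'
#' @param x cells-by-genes expression matrix.
#' @param min_cells minimum number of cells a gene must be expressed in.
#' @param min_genes minimum number of expressed genes per cell.
#' @return filtered expression matrix.
#' @export
filter_matrix <- function(x, min_cells = 1L, min_genes = 1L) {
  validate_expression_matrix(x)
  keep_cells <- rowSums(x > 0) >= min_genes
  keep_genes <- colSums(x > 0) >= min_cells
  if (!any(keep_cells) || !any(keep_genes)) {
    stop_validation("filtering removed all cells or all genes")
  }
  out <- x[keep_cells, keep_genes, drop = FALSE]
  attr(out, "log_transformed") <- attr(x, "log_transformed")
  out
}

#' Select the most variable genes
#'
#' Ranks genes by their sample standard deviation across cells and keeps
#' the `n_top` largest; ties are broken by original column order. The
#' default of 2000 genes matches the usual variable-gene budget for this
#' kind of model.
#'
#' @param x cells-by-genes expression matrix.
#' @param n_top number of genes to keep (capped at the number present).
#' @return expression matrix restricted to the selected genes, ordered by
#'   decreasing standard deviation.
#' @export
select_top_genes <- function(x, n_top = 2000L) {
  validate_expression_matrix(x)
  if (n_top < 1L) stop_validation("n_top must be >= 1")
  sds <- apply(x, 2L, sd)
  n_keep <- min(as.integer(n_top), ncol(x))
  # order(): decreasing sd, ties resolved by column position
  ord <- order(-sds, seq_along(sds))[seq_len(n_keep)]
  out <- x[, ord, drop = FALSE]
  attr(out, "log_transformed") <- attr(x, "log_transformed")
  out
}

#' Log-normalize an expression matrix
#'
#' Replaces each value x with log(1 + x) (natural log). Applying it twice
#' is an error: the `log_transformed` attribute tracks state.
#'
#' @param x cells-by-genes expression matrix.
#' @return log-transformed matrix with `log_transformed = TRUE`.
#' @export
log_normalize <- function(x) {
  validate_expression_matrix(x)
  if (isTRUE(attr(x, "log_transformed"))) {
    stop_validation("matrix is already log-transformed")
  }
  out <- log1p(x)
  dimnames(out) <- dimnames(x)
  attr(out, "log_transformed") <- TRUE
  out
}

#' Simulate dropout by masking non-zero entries
#'
#' Implements the evaluation protocol for imputation: a fraction `rate`
#' of the strictly positive entries (exactly `floor(rate * nnz)` of them)
#' is chosen uniformly at random and set to zero. The returned mask
#' records positions and original values so the matrix can be restored
#' and imputation can be scored at exactly the masked entries.
#'
#' @param x cells-by-genes expression matrix with at least one positive
#'   entry.
#' @param rate fraction in (0, 1) of non-zero entries to zero out.
#' @param seed integer seed; identical seeds give identical masks.
#' @return list with elements `matrix` (masked copy of `x`) and `mask`, a
#'   `dropout_mask` object: data frame of (cell, gene, value) plus `rate`
#'   and `seed` attributes.
#' @export
simulate_dropout <- function(x, rate = 0.1, seed = 1L) {
  validate_expression_matrix(x)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0 || rate >= 1) {
    stop_validation("rate must lie strictly between 0 and 1")
  }
  pos <- which(x > 0)
  if (length(pos) == 0L) stop_validation("matrix has no positive entries to mask")
  n_mask <- floor(rate * length(pos))
  if (n_mask < 1L) stop_validation("rate too small: no entries would be masked")
  set.seed(as.integer(seed))
  chosen <- sort(sample(pos, n_mask, replace = FALSE))
  idx <- arrayInd(chosen, dim(x))
  mask <- data.frame(cell = idx[, 1L], gene = idx[, 2L], value = x[chosen])
  attr(mask, "rate") <- rate
  attr(mask, "seed") <- as.integer(seed)
  class(mask) <- c("dropout_mask", class(mask))
  masked <- x
  masked[chosen] <- 0
  attr(masked, "log_transformed") <- attr(x, "log_transformed")
  list(matrix = masked, mask = mask)
}

#' Undo a simulated dropout mask
#'
#' Writes the recorded original values back into their positions;
#' `restore_dropout(simulate_dropout(x, r, s)$matrix, mask)` reproduces
#' `x` exactly.
#'
#' @param x masked expression matrix.
#' @param mask `dropout_mask` from [simulate_dropout()].
#' @return restored matrix.
#' @export
restore_dropout <- function(x, mask) {
  validate_expression_matrix(x)
  if (!inherits(mask, "dropout_mask")) stop_validation("mask must be a dropout_mask")
  x[cbind(mask$cell, mask$gene)] <- mask$value
  x
}

#' Extract matrix values at the masked positions
#'
#' @param x expression matrix.
#' @param mask `dropout_mask`.
#' @return numeric vector of `x` values at the masked entries, in mask
#'   order.
#' @export
masked_values <- function(x, mask) {
  if (!inherits(mask, "dropout_mask")) stop_validation("mask must be a dropout_mask")
  x[cbind(mask$cell, mask$gene)]
}
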