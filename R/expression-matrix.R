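# Expression matrices are plain base matrices, cells in rows and genes in
# columns, with unique rownames (cell ids) and colnames (gene ids) and a
# "log_transformed" attribute. Everything downstream indexes X[cell, gene].

#' Validate an expression matrix
#'
#' Checks the container contract used throughout the package: a numeric
#' cells-by-genes matrix, nonnegative, finite, with unique row (cell) and
#' column (gene) names.
#'
#' @param x matrix to validate.
#' @param allow_negative permit negative entries (used internally for
#'   reconstructions before clamping).
#' @return `x`, invisibly, with a `log_transformed` attribute (defaulting
#'   to `FALSE` when absent).
#' @export
validate_expression_matrix <- function(x, allow_negative = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_validation("expression matrix must be a numeric matrix")
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop_validation("expression matrix must have at least one cell and one gene")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop_validation("expression matrix contains missing or non-finite values")
  }
  if (!allow_negative && any(x < 0)) {
    stop_validation("expression matrix contains negative values")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_validation("expression matrix must carry cell (row) and gene (column) ids")
  }
  if (anyDuplicated(rownames(x))) stop_validation("duplicate cell ids")
  if (anyDuplicated(colnames(x))) stop_validation("duplicate gene ids")
  if (is.null(attr(x, "log_transformed"))) attr(x, "log_transformed") <- FALSE
  invisible(x)
}

as_expression_matrix <- function(values, cell_ids, gene_ids, log_transformed = FALSE) {
  x <- as.matrix(values)
  rownames(x) <- cell_ids
  colnames(x) <- gene_ids
  attr(x, "log_transformed") <- log_transformed
  validate_expression_matrix(x)
  x
}

mtx_sidecars <- function(path) {
  base <- sub("\\.mtx$", "", path)
  c(genes = paste0(base, "_genes.txt"), cells = paste0(base, "_cells.txt"))
}

#' Read an expression matrix from CSV, TSV or MatrixMarket
#'
#' Dense CSV/TSV files carry gene ids in the header row and cell ids in
#' the first column (transposed when `orientation = "genes_by_cells"`).
#' MatrixMarket (`.mtx`) files need two sidecar files next to the matrix,
#' `<stem>_genes.txt` and `<stem>_cells.txt`, one id per line.
#'
#' @param path file to read.
#' @param format one of `"csv"`, `"tsv"`, `"mtx"`. Defaults from the file
#'   extension.
#' @param orientation layout on disk; the returned matrix is always
#'   cells x genes.
#' @return a validated cells-by-genes expression matrix.
#' @export
read_matrix <- function(path,
                        format = c("csv", "tsv", "mtx"),
                        orientation = c("cells_by_genes", "genes_by_cells")) {
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "tsv", "mtx")) ext else "csv"
  }
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_format("file not found: ", path)

  if (format == "mtx") {
    side <- mtx_sidecars(path)
    if (!all(file.exists(side))) {
      stop_format("MTX sidecar files missing: ", paste(side[!file.exists(side)], collapse = ", "))
    }
    m <- tryCatch(as.matrix(Matrix::readMM(path)),
                  error = function(e) stop_format("failed to parse MTX: ", conditionMessage(e)))
    genes <- readLines(side["genes"])
    cells <- readLines(side["cells"])
    if (orientation == "genes_by_cells") m <- t(m)
    if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
      stop_format("MTX dimensions do not match sidecar id counts")
    }
    return(as_expression_matrix(m, cells, genes))
  }

  sep <- if (format == "csv") "," else "\t"
  df <- tryCatch(
    read.delim(path, sep = sep, header = TRUE, row.names = 1, check.names = FALSE),
    error = function(e) stop_format("failed to parse ", format, ": ", conditionMessage(e))
  )
  m <- as.matrix(df)
  if (!is.numeric(m)) stop_format("non-numeric entries in ", path)
  if (orientation == "genes_by_cells") m <- t(m)
  as_expression_matrix(m, rownames(m), colnames(m))
}

#' Write an expression matrix to CSV, TSV or MatrixMarket
#'
#' Inverse of [read_matrix()]; `read_matrix(write_matrix(x, p), ...)`
#' round-trips values and ids exactly (up to numeric printing for dense
#' text formats, which uses full precision).
#'
#' @inheritParams read_matrix
#' @param x cells-by-genes expression matrix.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path,
                         format = c("csv", "tsv", "mtx"),
                         orientation = c("cells_by_genes", "genes_by_cells")) {
  validate_expression_matrix(x)
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "tsv", "mtx")) ext else "csv"
  }
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  out <- if (orientation == "genes_by_cells") t(x) else x
  if (format == "mtx") {
    side <- mtx_sidecars(path)
    sp <- Matrix::Matrix(matrix(as.numeric(out), nrow(out), ncol(out)), sparse = TRUE)
    Matrix::writeMM(sp, path)
    writeLines(rownames(x), side["cells"])
    writeLines(colnames(x), side["genes"])
    return(invisible(path))
  }
  df <- as.data.frame(out)
  utils::write.table(df, path, sep = if (format == "csv") "," else "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read / write cell cluster labels
#'
#' Labels travel as a two-column CSV (`cell_id,label`).
#'
#' @param path CSV file.
#' @return named vector of labels (names are cell ids).
#' @export
read_labels <- function(path) {
  df <- read.csv(path, header = TRUE, check.names = FALSE)
  if (ncol(df) < 2L) stop_format("label file must have two columns (cell_id, label)")
  stats::setNames(df[[2L]], as.character(df[[1L]]))
}

#' @rdname read_labels
#' @param labels named vector (names = cell ids) or unnamed vector plus
#'   `cell_ids`.
#' @param cell_ids cell identifiers when `labels` is unnamed.
#' @export
write_labels <- function(labels, path, cell_ids = names(labels)) {
  if (is.null(cell_ids)) stop_validation("labels need cell ids")
  write.csv(data.frame(cell_id = cell_ids, label = unname(labels)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
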