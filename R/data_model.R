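#' Expression matrix container
#'
#' Bundles a dense rows-by-genes matrix of expression values with gene and
#' row (cell or spot) identifiers and a layer tag recording whether the
#' values are raw counts or log-normalized.
#'
#' @param values Numeric matrix, rows are cells or spots, columns are genes.
#' @param gene_ids Character vector of unique gene symbols, one per column.
#'   Defaults to `colnames(values)`.
#' @param row_ids Character vector of cell/spot identifiers, one per row.
#'   Defaults to `rownames(values)`, or `row1..rowN` when absent.
#' @param layer Either `"raw"` (non-negative counts) or `"lognorm"`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `row_ids`, `layer`.
#' @export
expression_matrix <- function(values, gene_ids = NULL, row_ids = NULL,
                              layer = c("raw", "lognorm")) {
  layer <- match.arg(layer)
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(gene_ids)) gene_ids <- colnames(values)
  if (is.null(row_ids)) row_ids <- rownames(values)
  if (is.null(gene_ids)) stop("gene identifiers are required (columns unnamed)")
  if (is.null(row_ids)) row_ids <- paste0("row", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids)
  row_ids <- as.character(row_ids)
  if (length(gene_ids) != ncol(values)) {
    stop("length(gene_ids) must equal ncol(values)")
  }
  if (length(row_ids) != nrow(values)) {
    stop("length(row_ids) must equal nrow(values)")
  }
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (layer == "raw" && any(values < 0)) {
    stop("raw counts must be non-negative")
  }
  dimnames(values) <- list(row_ids, gene_ids)
  structure(
    list(values = values, gene_ids = gene_ids, row_ids = row_ids,
         layer = layer),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d rows x %d genes\n",
              x$layer, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Spatial coordinates container
#'
#' @param coords Numeric matrix with two columns (x, y), one row per spot or
#'   cell, in the source units of the assay.
#' @param row_ids Identifiers aligned with the rows of an
#'   [expression_matrix()]. Defaults to `rownames(coords)`.
#'
#' @return A `SpatialCoords` object (list with `coords`, `row_ids`).
#' @export
spatial_coords <- function(coords, row_ids = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2) stop("coordinates must have exactly two columns")
  if (!is.numeric(coords) || any(!is.finite(coords))) {
    stop("coordinates must be finite numeric values")
  }
  if (is.null(row_ids)) row_ids <- rownames(coords)
  if (is.null(row_ids)) row_ids <- paste0("row", seq_len(nrow(coords)))
  row_ids <- as.character(row_ids)
  if (length(row_ids) != nrow(coords)) {
    stop("length(row_ids) must equal nrow(coords)")
  }
  colnames(coords) <- c("x", "y")
  rownames(coords) <- row_ids
  structure(list(coords = coords, row_ids = row_ids),
            class = "SpatialCoords")
}

#' @export
print.SpatialCoords <- function(x, ...) {
  cat(sprintf("SpatialCoords: %d points\n", nrow(x$coords)))
  invisible(x)
}

#' Library-size normalize and log-transform raw counts
#'
#' Each row is scaled to a common library size of 10,000 and transformed as
#' `log(1 + 1e4 * x_ij / sum_j x_ij)`, the standard CP10K/log1p
#' normalization used throughout single-cell analysis.
#'
#' @param x An [expression_matrix()] with `layer = "raw"`.
#' @param drop_empty Drop rows whose total count is zero (with a warning
#'   naming them). When `FALSE`, a zero-total row is an error.
#'
#' @return An `ExpressionMatrix` with `layer = "lognorm"`.
#' @export
normalize_expression <- function(x, drop_empty = TRUE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$layer != "raw") stop("normalize_expression expects a raw-count layer")
  totals <- rowSums(x$values)
  empty <- totals <= 0
  if (any(empty)) {
    if (!drop_empty) {
      stop(sprintf("row(s) with zero total counts: %s",
                   paste(x$row_ids[empty], collapse = ", ")))
    }
    warning(sprintf("dropping %d zero-count row(s): %s", sum(empty),
                    paste(x$row_ids[empty], collapse = ", ")))
    x$values <- x$values[!empty, , drop = FALSE]
    x$row_ids <- x$row_ids[!empty]
    totals <- totals[!empty]
  }
  out <- log1p(1e4 * x$values / totals)
  expression_matrix(out, gene_ids = x$gene_ids, row_ids = x$row_ids,
                    layer = "lognorm")
}

#' Restrict two expression matrices to a shared, identically ordered gene set
#'
#' @param sc,st [expression_matrix()] objects.
#' @param gene_set Optional character vector fixing the genes and their
#'   order; it is intersected with both matrices' genes (order preserved).
#'   By default the intersection in `sc`'s gene order is used. Matching is
#'   exact and case-sensitive.
#'
#' @return A list with elements `sc` and `st`, both restricted to identical
#'   `gene_ids` in identical order.
#' @export
align_genes <- function(sc, st, gene_set = NULL) {
  stopifnot(inherits(sc, "ExpressionMatrix"), inherits(st, "ExpressionMatrix"))
  shared <- intersect(sc$gene_ids, st$gene_ids)
  if (!is.null(gene_set)) {
    shared <- gene_set[gene_set %in% shared]
  }
  if (length(shared) == 0) stop("no genes shared between the two matrices")
  take <- function(x) {
    expression_matrix(x$values[, shared, drop = FALSE], gene_ids = shared,
                      row_ids = x$row_ids, layer = x$layer)
  }
  list(sc = take(sc), st = take(st))
}

#' Select highly variable genes by binned normalized dispersion
#'
#' Ranks genes by the dispersion (variance/mean) of their log-normalized
#' values, z-scored within 20 equal-width bins of the per-gene mean
#' (Seurat-flavour highly-variable-gene selection). Deterministic: ties are
#' broken by gene id.
#'
#' @param x An [expression_matrix()] with `layer = "lognorm"`.
#' @param n_genes Number of genes to return (at most the gene count).
#' @param n_bins Number of mean bins (default 20).
#'
#' @return Character vector of `n_genes` gene ids, most variable first.
#' @export
select_variable_genes <- function(x, n_genes, n_bins = 20) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$layer != "lognorm") stop("select_variable_genes expects lognorm layer")
  h <- ncol(x$values)
  if (n_genes > h) stop("n_genes exceeds the number of genes")
  mu <- colMeans(x$values)
  v <- apply(x$values, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # equal-width bins over the observed mean range
  brk <- seq(min(mu), max(mu), length.out = n_bins + 1)
  bin <- findInterval(mu, brk, rightmost.closed = TRUE, all.inside = TRUE)
  nd <- disp
  for (b in unique(bin)) {
    idx <- bin == b
    m <- mean(disp[idx])
    s <- stats::sd(disp[idx])
    nd[idx] <- if (!is.na(s) && s > 0) (disp[idx] - m) / s else 0
  }
  nd[disp == 0] <- -Inf   # constant genes always rank last
  ord <- order(-nd, x$gene_ids)
  x$gene_ids[ord][seq_len(n_genes)]
}

#' One-hot encode per-row cell-type labels
#'
#' @param labels Character (or factor) vector of cell-type labels, no
#'   missing or empty entries.
#'
#' @return A `CellTypeAnnotation` object: list with `labels` (character),
#'   `indicator` (rows-by-types 0/1 matrix whose columns are the sorted
#'   unique labels; each row sums to exactly 1).
#' @export
one_hot_annotation <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0) stop("labels must be non-empty")
  if (anyNA(labels) || any(labels == "")) {
    stop("labels must not contain missing or empty entries")
  }
  types <- sort(unique(labels))
  ind <- matrix(0L, nrow = length(labels), ncol = length(types),
                dimnames = list(NULL, types))
  ind[cbind(seq_along(labels), match(labels, types))] <- 1L
  structure(list(labels = labels, indicator = ind),
            class = "CellTypeAnnotation")
}

#' @export
print.CellTypeAnnotation <- function(x, ...) {
  cat(sprintf("CellTypeAnnotation: %d rows, %d types\n",
              length(x$labels), ncol(x$indicator)))
  invisible(x)
}

# ---- file I/O ---------------------------------------------------------------

#' Read an expression matrix from a delimited table
#'
#' Comma-separated, header row of gene ids, first column the row (cell/spot)
#' id.
#'
#' @param path CSV file path.
#' @param layer Layer tag of the stored values (`"raw"` or `"lognorm"`).
#' @return An [expression_matrix()].
#' @export
read_expression_csv <- function(path, layer = "raw") {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  expression_matrix(as.matrix(df), gene_ids = colnames(df),
                    row_ids = rownames(df), layer = layer)
}

#' Write an expression matrix to CSV (header = genes, first column = row id)
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression_csv <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  utils::write.csv(as.data.frame(x$values), path, row.names = TRUE)
  invisible(path)
}

#' Read an expression matrix from Matrix-Market triplets plus id sidecars
#'
#' @param mtx_path `.mtx` file (rows = cells/spots, columns = genes).
#' @param rows_path Text file, one row id per line.
#' @param genes_path Text file, one gene id per line.
#' @param layer Layer tag.
#' @return An [expression_matrix()].
#' @export
read_expression_mtx <- function(mtx_path, rows_path, genes_path,
                                layer = "raw") {
  m <- as.matrix(Matrix::readMM(mtx_path))
  row_ids <- readLines(rows_path)
  gene_ids <- readLines(genes_path)
  expression_matrix(m, gene_ids = gene_ids, row_ids = row_ids, layer = layer)
}

#' Read spot/cell coordinates from CSV (columns: id, x, y)
#' @param path CSV path with a header; first column is the row id.
#' @return A [spatial_coords()] object.
#' @export
read_coords_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  if (ncol(df) < 2) stop(sprintf("%s: expected columns id,x,y", path))
  spatial_coords(as.matrix(df[, 1:2]), row_ids = rownames(df))
}

#' Write coordinates to CSV
#' @param y A [spatial_coords()] object.
#' @param path Output path.
#' @export
write_coords_csv <- function(y, path) {
  stopifnot(inherits(y, "SpatialCoords"))
  utils::write.csv(as.data.frame(y$coords), path, row.names = TRUE)
  invisible(path)
}
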