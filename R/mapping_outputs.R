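.stochastic_mat <- function(m, name = "matrix", tol = 1e-6) {
  m <- as.matrix(m)
  if (any(m < -tol)) stop(sprintf("%s has negative entries", name))
  if (any(abs(rowSums(m) - 1) > tol)) {
    stop(sprintf("%s rows must sum to 1", name))
  }
  m
}

#' Deconvolve spots into cell-type proportions
#'
#' `T^ST = Chat %*% T^SC`: each spot's distribution over cells, summed by
#' the cells' one-hot type indicators, gives a valid per-spot proportion
#' vector.
#'
#' @param chat N-by-M row-stochastic ST-to-SC mapping (see
#'   [cross_mapping()]).
#' @param t_sc A [one_hot_annotation()] for the M cells.
#' @return A `DeconvolutionResult`: list with `proportions` (N-by-D, rows
#'   sum to 1) and `cell_types` (sorted labels, the column order).
#' @export
deconvolve <- function(chat, t_sc) {
  stopifnot(inherits(t_sc, "CellTypeAnnotation"))
  chat <- .stochastic_mat(chat, "Chat")
  if (ncol(chat) != nrow(t_sc$indicator)) {
    stop("Chat columns must match the number of annotated cells")
  }
  props <- chat %*% t_sc$indicator
  structure(list(proportions = props, cell_types = colnames(t_sc$indicator)),
            class = "DeconvolutionResult")
}

#' @export
print.DeconvolutionResult <- function(x, ...) {
  cat(sprintf("DeconvolutionResult: %d spots x %d types (%s)\n",
              nrow(x$proportions), length(x$cell_types),
              paste(x$cell_types, collapse = ", ")))
  invisible(x)
}

#' Pseudo spatial coordinates of single cells
#'
#' `Y^SC = C %*% Y^ST`: each cell is placed at the weighted mean of the
#' spot coordinates under its mapping distribution, hence inside the convex
#' hull of the spots.
#'
#' @param c_mat M-by-N row-stochastic SC-to-ST mapping.
#' @param y_st [spatial_coords()] of the N spots.
#' @return A [spatial_coords()] with one point per cell.
#' @export
pseudo_coordinates <- function(c_mat, y_st) {
  stopifnot(inherits(y_st, "SpatialCoords"))
  c_mat <- .stochastic_mat(c_mat, "C")
  if (ncol(c_mat) != nrow(y_st$coords)) {
    stop("C columns must match the number of spots")
  }
  ids <- rownames(c_mat)
  if (is.null(ids)) ids <- paste0("cell", seq_len(nrow(c_mat)))
  spatial_coords(c_mat %*% y_st$coords, row_ids = ids)
}

#' Cell-cell spatial adjacency from SC embeddings
#'
#' The raw Gram matrix `<Z^SC_i, Z^SC_j>`. It is consumed downstream only
#' through per-row rankings (e.g. [hit_number()]), so no normalization is
#' applied.
#'
#' @param z_sc SC [embeddings()] (or matrix) with at least 2 rows.
#' @return Symmetric M-by-M matrix of inner products.
#' @export
sc_adjacency <- function(z_sc) {
  z <- .embed_mat(z_sc)
  if (nrow(z) < 2) stop("at least two cells are required")
  tcrossprod(z)
}

#' Transfer a per-spot annotation to cells
#'
#' `score_cell = C %*% v`: cells inherit the mapping-weighted mean of a
#' per-spot scalar (e.g. a liver zonation score), so transferred values
#' stay within the range of the spot values.
#'
#' @param c_mat M-by-N row-stochastic SC-to-ST mapping.
#' @param v_st Numeric vector of length N.
#' @return Numeric vector of length M.
#' @export
transfer_spot_annotation <- function(c_mat, v_st) {
  c_mat <- .stochastic_mat(c_mat, "C")
  if (length(v_st) != ncol(c_mat)) {
    stop("annotation length must equal the number of spots")
  }
  drop(c_mat %*% v_st)
}

#' Unify an arbitrary non-negative mapping matrix into coordinates and ranks
#'
#' Accepts any externally produced cell-to-spot weight matrix, row-
#' normalizes it, derives per-cell coordinates (`C %*% Y`) and a ranked
#' cell-cell neighbor matrix from the pairwise Euclidean distances of those
#' coordinates (closest pair ranked 1; ties broken by smaller index; self
#' excluded). Cells whose row sums to zero are flagged unmapped and
#' excluded from the ranking.
#'
#' @param c_any M-by-N non-negative matrix.
#' @param y_st [spatial_coords()] of the N spots.
#' @return List: `coords` ([spatial_coords()], NA rows for unmapped cells),
#'   `ranks` (M-by-M rank matrix, NA for unmapped cells, 0 on the
#'   diagonal), `unmapped` (integer indices of zero rows).
#' @export
unify_mapping <- function(c_any, y_st) {
  stopifnot(inherits(y_st, "SpatialCoords"))
  c_any <- as.matrix(c_any)
  if (any(c_any < 0)) stop("mapping weights must be non-negative")
  if (ncol(c_any) != nrow(y_st$coords)) {
    stop("mapping columns must match the number of spots")
  }
  rs <- rowSums(c_any)
  unmapped <- which(rs == 0)
  m <- nrow(c_any)
  coords <- matrix(NA_real_, m, 2)
  ok <- rs > 0
  coords[ok, ] <- (c_any[ok, , drop = FALSE] / rs[ok]) %*% y_st$coords
  ranks <- matrix(NA_real_, m, m)
  if (sum(ok) >= 2) {
    d <- as.matrix(stats::dist(coords[ok, , drop = FALSE]))
    sub <- matrix(0, sum(ok), sum(ok))
    for (i in seq_len(sum(ok))) {
      others <- setdiff(seq_len(sum(ok)), i)
      ord <- others[order(d[i, others], others)]
      sub[i, ord] <- seq_along(ord)
    }
    ranks[ok, ok] <- sub
  }
  ids <- rownames(c_any)
  if (is.null(ids)) ids <- paste0("cell", seq_len(m))
  rownames(coords) <- ids
  if (length(unmapped)) {
    warning(sprintf("%d unmapped cell(s) (zero mapping rows) excluded from ranking",
                    length(unmapped)))
  }
  coords_obj <- structure(list(coords = coords, row_ids = ids),
                          class = "SpatialCoords")
  list(coords = coords_obj, ranks = ranks, unmapped = unmapped)
}
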