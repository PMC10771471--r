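#' Mean Euclidean error between predicted and true coordinates
#'
#' `(1/M) * sum_i sqrt((dx_i)^2 + (dy_i)^2)` over paired rows.
#'
#' @param y_true,y_pred [spatial_coords()] with equal row counts in the
#'   same order.
#' @param subset Optional logical/integer subset of rows to score (e.g.
#'   the covered vs uncovered cells of a [generate_pseudo_st()] run).
#' @return Non-negative scalar; 0 iff identical coordinates.
#' @export
coordinate_mae <- function(y_true, y_pred, subset = NULL) {
  a <- y_true$coords; b <- y_pred$coords
  if (nrow(a) != nrow(b)) stop("coordinate sets differ in row count")
  if (!is.null(subset)) {
    a <- a[subset, , drop = FALSE]; b <- b[subset, , drop = FALSE]
  }
  mean(sqrt(rowSums((a - b)^2)))
}

.topk_sets <- function(score_mat, k, decreasing) {
  m <- nrow(score_mat)
  lapply(seq_len(m), function(i) {
    others <- setdiff(seq_len(m), i)
    s <- score_mat[i, others]
    ord <- if (decreasing) order(-s, others) else order(s, others)
    others[ord][seq_len(k)]
  })
}

#' Neighbor hit number of a predicted cell-cell adjacency
#'
#' For each cell, the k nearest cells by true coordinates (self excluded)
#' are compared with the k largest entries of the cell's predicted
#' adjacency row (self excluded; ties broken by index). The hit number is
#' the mean overlap, between 0 and k, and is invariant to any strictly
#' monotone transform of the prediction rows.
#'
#' @param y_true [spatial_coords()] of the M cells.
#' @param pred_adjacency M-by-M matrix scoring cell-cell proximity (larger
#'   = closer), e.g. [sc_adjacency()].
#' @param k Number of neighbors, `1 <= k <= M - 1`.
#' @param subset Optional subset of cells to average over (neighbor sets
#'   are still drawn from all cells).
#' @return Mean conserved-neighbor count.
#' @export
hit_number <- function(y_true, pred_adjacency, k, subset = NULL) {
  stopifnot(inherits(y_true, "SpatialCoords"))
  m <- nrow(y_true$coords)
  pred_adjacency <- as.matrix(pred_adjacency)
  if (!all(dim(pred_adjacency) == c(m, m))) {
    stop("pred_adjacency must be M x M matching the coordinates")
  }
  if (k < 1 || k > m - 1) stop("k must satisfy 1 <= k <= M - 1")
  d <- as.matrix(stats::dist(y_true$coords))
  truth <- .topk_sets(d, k, decreasing = FALSE)
  pred <- .topk_sets(pred_adjacency, k, decreasing = TRUE)
  hits <- vapply(seq_len(m), function(i) {
    length(intersect(truth[[i]], pred[[i]]))
  }, numeric(1))
  if (!is.null(subset)) hits <- hits[subset]
  mean(hits)
}

#' Per-type Pearson correlation of mapped cell-type distributions
#'
#' For each cell type, the rows of the SC-to-ST mapping belonging to that
#' type are summed column-wise into an estimated spatial distribution over
#' spots, which is correlated with the true per-spot proportion of the
#' type. A zero-variance vector on either side yields 0 with a warning.
#'
#' @param c_mat M-by-N row-stochastic SC-to-ST mapping.
#' @param labels [one_hot_annotation()] (or label vector) for the M cells.
#' @param p_true N-by-A matrix of true per-spot proportions with type
#'   column names (e.g. `true_proportions` of a [generate_pseudo_st()]
#'   run).
#' @return Named numeric vector of correlations, one per type present in
#'   `labels`.
#' @export
celltype_pcc <- function(c_mat, labels, p_true) {
  if (!inherits(labels, "CellTypeAnnotation")) labels <- one_hot_annotation(labels)
  c_mat <- as.matrix(c_mat)
  types <- colnames(labels$indicator)
  if (!all(types %in% colnames(p_true))) {
    stop("label type(s) missing from the true proportion columns")
  }
  if (nrow(c_mat) != length(labels$labels)) {
    stop("mapping rows must match the number of labelled cells")
  }
  if (ncol(c_mat) != nrow(p_true)) {
    stop("mapping columns must match the number of spots")
  }
  out <- stats::setNames(numeric(length(types)), types)
  for (ty in types) {
    est <- colSums(c_mat[labels$labels == ty, , drop = FALSE])
    tru <- p_true[, ty]
    if (stats::sd(est) == 0 || stats::sd(tru) == 0) {
      warning(sprintf("type '%s': zero-variance distribution, PCC set to 0", ty))
      out[ty] <- 0
    } else {
      out[ty] <- stats::cor(est, tru)
    }
  }
  out
}

#' Sphere-inclusion profile for detecting hollow embedding geometry
#'
#' Spheres are grown around the mean embedding and the fraction of points
#' they include is tracked. The radius axis is normalized by D, the mean
#' nearest-neighbor distance within the point set (the data's own
#' resolution scale, the same convention the spatial kernel bandwidth
#' uses), so profiles of different embeddings are comparable. A hollow
#' embedding keeps the included fraction low at small normalized radii:
#' no points sit within a few neighbor-spacings of the centroid.
#'
#' @param z [embeddings()] or matrix with at least 2 rows.
#' @param radii Ascending normalized radii.
#' @return Named numeric vector, fraction per radius (non-decreasing).
#' @export
hollow_profile <- function(z, radii = seq(0, 20, by = 0.5)) {
  zm <- .embed_mat(z)
  if (nrow(zm) < 2) stop("at least two points are required")
  if (is.unsorted(radii)) stop("radii must be sorted ascending")
  center <- colMeans(zm)
  d <- sqrt(rowSums(sweep(zm, 2, center)^2))
  pd <- as.matrix(stats::dist(zm)); diag(pd) <- Inf
  scale_d <- mean(apply(pd, 1, min))
  if (scale_d == 0) {
    stop("all points coincide; nearest-neighbor scale D undefined")
  }
  stats::setNames(vapply(radii, function(r) mean(d <= r * scale_d), numeric(1)),
                  as.character(radii))
}

#' Bundle the three benchmark metrics into one report
#'
#' @param y_true True cell coordinates ([spatial_coords()]).
#' @param y_pred Predicted cell coordinates.
#' @param pred_adjacency Predicted cell-cell adjacency matrix.
#' @param c_mat SC-to-ST mapping matrix.
#' @param labels Cell-type annotation.
#' @param p_true True per-spot proportions.
#' @param k_values Neighbor counts for the hit curve.
#' @param subset Optional cell subset (e.g. covered cells only).
#' @return An `EvaluationReport` list: `mae`, `hit_curve` (named by k),
#'   `per_type_pcc`, `median_pcc`.
#' @export
evaluation_report <- function(y_true, y_pred, pred_adjacency, c_mat, labels,
                              p_true, k_values = c(10, 20, 50), subset = NULL) {
  hit <- vapply(k_values, function(k) {
    hit_number(y_true, pred_adjacency, k, subset = subset)
  }, numeric(1))
  pcc <- celltype_pcc(c_mat, labels, p_true)
  structure(list(mae = coordinate_mae(y_true, y_pred, subset = subset),
                 hit_curve = stats::setNames(hit, as.character(k_values)),
                 per_type_pcc = pcc, median_pcc = stats::median(pcc)),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport: MAE %.3f, median PCC %.3f\n",
              x$mae, x$median_pcc))
  cat("  hit curve:",
      paste(sprintf("k=%s: %.2f", names(x$hit_curve), x$hit_curve),
            collapse = ", "), "\n")
  invisible(x)
}
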