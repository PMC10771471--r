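#' Integrated-gradient attribution of a scalar function
#'
#' Path-integral attribution from the all-zero baseline to the input:
#' `W_j = x_j * (1/steps) * sum_t df(alpha_t * x)/dx_j` with midpoint
#' nodes `alpha_t = (t - 0.5)/steps` on `[0, 1]`. As `steps` grows the
#' attributions satisfy the completeness axiom
#' `sum_j W_j -> f(x) - f(0)`; the residual is reported as
#' `convergence_gap`, never hidden.
#'
#' @param x Numeric input vector (gene expression of one cell).
#' @param f Scalar-valued function of an input vector.
#' @param steps Number of quadrature steps (default 50).
#' @param grad_f Optional gradient function returning `df/dx` at a point;
#'   when absent the gradient is taken by central finite differences.
#' @param eps Finite-difference step (used only without `grad_f`).
#' @return List: `attribution` (vector like `x`), `convergence_gap`.
#' @export
integrated_gradients <- function(x, f, steps = 50L, grad_f = NULL,
                                 eps = 1e-5) {
  stopifnot(steps >= 1)
  x <- as.numeric(x)
  if (is.null(grad_f)) {
    grad_f <- function(v) {
      vapply(seq_along(v), function(j) {
        vp <- v; vm <- v
        vp[j] <- vp[j] + eps; vm[j] <- vm[j] - eps
        (f(vp) - f(vm)) / (2 * eps)
      }, numeric(1))
    }
  }
  g <- rep(0, length(x))
  for (t in seq_len(steps)) {
    alpha <- (t - 0.5) / steps
    gt <- grad_f(alpha * x)
    if (any(!is.finite(gt))) {
      stop(sprintf("non-finite gradient at integration step %d", t))
    }
    g <- g + gt
  }
  w <- x * g / steps
  gap <- abs(sum(w) - (f(x) - f(0 * x)))
  list(attribution = w, convergence_gap = gap)
}

# Analytic gradient machinery for the mapped-probability target
# f(x) = softmax_j(<encode(x), Z^ST_j>)[m], with frozen ST embeddings.
# Returns f values and gradients for a whole matrix of inputs at once.
.map_prob_forward <- function(params, x_mat, z_st, m_idx) {
  fw <- .mlp_forward(params, x_mat, NULL)
  s <- tcrossprod(fw$z, z_st)              # steps x N similarity
  p <- .row_softmax(s)
  list(fw = fw, p = p, f = p[, m_idx])
}

.map_prob_grad <- function(params, x_mat, z_st, m_idx) {
  pf <- .map_prob_forward(params, x_mat, z_st, m_idx)
  p <- pf$p
  # d p_m / d s_j = p_m (1[j=m] - p_j), per row
  ds <- -p * pf$f
  ds[, m_idx] <- ds[, m_idx] + pf$f
  dz <- ds %*% z_st
  dx <- .mlp_backward(params, pf$fw, dz)$dx
  list(f = pf$f, dx = dx)
}

#' Gene attribution profile of all cells in a trained model
#'
#' For every cell i the target is `C[i, m]`, the cell's largest mapping
#' probability (m = argmax of row i of the SC-to-ST mapping), recomputed as
#' a differentiable function of the cell's expression with the ST
#' embeddings frozen. Attribution is by [integrated_gradients()] with the
#' encoder's analytic gradient; genes at zero expression receive
#' attribution 0 by construction.
#'
#' @param sc Log-normalized [expression_matrix()] of the cells (gene order
#'   must match the model input).
#' @param fit A `StemFit` from [train_stem()] (or a list with `model` and
#'   `z_st`).
#' @param steps Integration steps (default 50).
#' @param cells Optional integer subset of cells to attribute.
#' @return An `AttributionProfile`: `scores` (cells-by-genes), `target_spot`
#'   (argmax spot per cell), `convergence_gap` (per cell), `gene_ids`,
#'   `cell_ids`.
#' @export
attribution_profile <- function(sc, fit, steps = 50L, cells = NULL) {
  x <- .expr_mat(sc)
  params <- fit$model$params
  z_st <- .embed_mat(fit$z_st)
  if (ncol(x) != fit$model$cfg$n_genes) {
    stop("gene count does not match the trained model")
  }
  z_sc <- .mlp_forward(params, x, NULL)$z
  c_mat <- .row_softmax(tcrossprod(z_sc, z_st))
  targets <- max.col(c_mat, ties.method = "first")
  if (is.null(cells)) cells <- seq_len(nrow(x))
  alphas <- (seq_len(steps) - 0.5) / steps
  scores <- matrix(0, length(cells), ncol(x))
  gaps <- numeric(length(cells))
  zero <- matrix(0, 1, ncol(x))
  for (ci in seq_along(cells)) {
    i <- cells[ci]
    m_idx <- targets[i]
    xs <- outer(alphas, x[i, ])
    gr <- .map_prob_grad(params, xs, z_st, m_idx)
    if (any(!is.finite(gr$dx))) {
      stop(sprintf("non-finite gradient while attributing cell %d", i))
    }
    w <- x[i, ] * colMeans(gr$dx)
    f_x <- .map_prob_forward(params, x[i, , drop = FALSE], z_st, m_idx)$f
    f_0 <- .map_prob_forward(params, zero, z_st, m_idx)$f
    scores[ci, ] <- w
    gaps[ci] <- abs(sum(w) - (f_x - f_0))
  }
  cell_ids <- if (inherits(sc, "ExpressionMatrix")) sc$row_ids[cells] else
    paste0("cell", cells)
  gene_ids <- if (inherits(sc, "ExpressionMatrix")) sc$gene_ids else
    colnames(x)
  dimnames(scores) <- list(cell_ids, gene_ids)
  structure(list(scores = scores, target_spot = targets[cells],
                 convergence_gap = gaps, gene_ids = gene_ids,
                 cell_ids = cell_ids),
            class = "AttributionProfile")
}

#' @export
print.AttributionProfile <- function(x, ...) {
  cat(sprintf("AttributionProfile: %d cells x %d genes (median completeness gap %.2e)\n",
              nrow(x$scores), ncol(x$scores), stats::median(x$convergence_gap)))
  invisible(x)
}

.poly_eval <- function(coefs, x) {
  drop(outer(x, seq_along(coefs) - 1, "^") %*% coefs)
}

.poly_deriv <- function(coefs) {
  if (length(coefs) <= 1) return(0)
  coefs[-1] * seq_len(length(coefs) - 1)
}

#' Fit a 1-D spatial trajectory and assign pseudotime by arc length
#'
#' Least-squares polynomial `y = p(x)` of the given degree through the
#' cell coordinates. The start cell (pseudotime 0) defaults to the cell at
#' the top-right corner (maximum x, ties by maximum y); every other cell's
#' pseudotime is the arc length of the curve between the start's and the
#' cell's x-coordinate, `int sqrt(1 + p'(t)^2) dt`, evaluated by adaptive
#' quadrature.
#'
#' @param coords [spatial_coords()] of the cells (at least `degree + 1`,
#'   x not all equal).
#' @param degree Polynomial degree (default 5).
#' @param start_rule `"top_right"` (default) or `"min_x"`.
#' @return A `SpatialTrajectory`: `coefficients` (ascending powers),
#'   `start_cell` (row id), `pseudotime` (named, >= 0), `residual`
#'   (squared error E of the fit).
#' @export
fit_trajectory <- function(coords, degree = 5L, start_rule = c("top_right", "min_x")) {
  stopifnot(inherits(coords, "SpatialCoords"))
  start_rule <- match.arg(start_rule)
  x <- coords$coords[, 1]; y <- coords$coords[, 2]
  if (length(x) < degree + 1) stop("need at least degree + 1 cells")
  if (length(unique(x)) < 2) stop("x-coordinates must not all be equal")
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  coefs <- stats::coef(fit)
  if (anyNA(coefs)) {
    stop("rank-deficient polynomial fit; try a lower degree")
  }
  names(coefs) <- NULL
  dcoefs <- .poly_deriv(coefs)
  speed <- function(t) sqrt(1 + .poly_eval(dcoefs, t)^2)
  start_idx <- switch(start_rule,
    top_right = order(-x, -y)[1],
    min_x = order(x, y)[1])
  x0 <- x[start_idx]
  # cumulative arc length over sorted unique x, interpolated per cell
  xs <- sort(unique(c(x, x0)))
  seg <- vapply(seq_along(xs)[-1], function(i) {
    stats::integrate(speed, xs[i - 1], xs[i], rel.tol = 1e-8)$value
  }, numeric(1))
  cum <- c(0, cumsum(seg))
  arc_at <- function(v) cum[match(v, xs)]
  pt <- abs(arc_at(x) - arc_at(x0))
  names(pt) <- coords$row_ids
  structure(list(coefficients = coefs, start_cell = coords$row_ids[start_idx],
                 pseudotime = pt, residual = sum(stats::resid(fit)^2),
                 degree = degree),
            class = "SpatialTrajectory")
}

#' @export
print.SpatialTrajectory <- function(x, ...) {
  cat(sprintf("SpatialTrajectory: degree %d, %d cells, start '%s', residual %.4g\n",
              x$degree, length(x$pseudotime), x$start_cell, x$residual))
  invisible(x)
}

#' Bin cells into trajectory segments
#'
#' Equal-width bins over the pseudotime range (the default, 11 segments,
#' follows the spinal-cord analysis setting); `"count"` gives equal-count
#' quantile bins instead.
#'
#' @param traj A [fit_trajectory()] result.
#' @param n_segments Number of segments (default 11).
#' @param method `"width"` (default) or `"count"`.
#' @return Integer vector of segment ids in `1..n_segments`, named by cell.
#' @export
segment_cells <- function(traj, n_segments = 11L, method = c("width", "count")) {
  stopifnot(inherits(traj, "SpatialTrajectory"), n_segments >= 2)
  method <- match.arg(method)
  pt <- traj$pseudotime
  rng <- range(pt)
  if (diff(rng) == 0) {
    warning("all cells share one pseudotime; assigning every cell to segment 1")
    return(stats::setNames(rep(1L, length(pt)), names(pt)))
  }
  brk <- if (method == "width") {
    seq(rng[1], rng[2], length.out = n_segments + 1)
  } else {
    unique(stats::quantile(pt, probs = seq(0, 1, length.out = n_segments + 1)))
  }
  seg <- findInterval(pt, brk, rightmost.closed = TRUE, all.inside = TRUE)
  stats::setNames(as.integer(seg), names(pt))
}

#' Call spatially dominant genes from attribution scores
#'
#' For every gene and trajectory segment, a one-sided Wilcoxon rank-sum
#' test compares the gene's attribution scores in the segment against the
#' union of all other segments (alternative: greater). p-values are
#' Benjamini-Hochberg adjusted across all gene-by-segment tests; rows with
#' adjusted p below `fdr` are returned. A gene is a spatially dominant
#' gene (SDG) if it is significant in at least one segment. The identical
#' machinery applies to an expression matrix, yielding the conventional
#' segment-wise differentially expressed genes for comparison.
#'
#' @param scores An `AttributionProfile` or a cells-by-genes numeric
#'   matrix.
#' @param segments Integer vector of per-cell segment ids (see
#'   [segment_cells()]).
#' @param fdr Adjusted-p threshold (default 0.05).
#' @return data.frame with columns `gene`, `segment`, `statistic`, `p`,
#'   `p_adj`, sorted by `p_adj`; zero rows when nothing passes.
#' @export
identify_sdgs <- function(scores, segments, fdr = 0.05) {
  mat <- if (inherits(scores, "AttributionProfile")) scores$scores else
    as.matrix(scores)
  if (length(segments) != nrow(mat)) {
    stop("segments must have one entry per cell")
  }
  tab <- table(segments)
  usable <- as.integer(names(tab)[tab >= 2])
  if (length(usable) < length(tab)) {
    warning("segment(s) with fewer than 2 cells excluded from testing")
  }
  genes <- colnames(mat)
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(mat)))
  res <- vector("list", length(usable) * ncol(mat))
  k <- 0L
  for (s in usable) {
    in_seg <- segments == s
    for (g in seq_len(ncol(mat))) {
      a <- mat[in_seg, g]; b <- mat[!in_seg, g]
      wt <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = "greater", exact = FALSE,
                           correct = TRUE))
      k <- k + 1L
      res[[k]] <- data.frame(gene = genes[g], segment = s,
                             statistic = unname(wt$statistic),
                             p = wt$p.value)
    }
  }
  out <- do.call(rbind, res[seq_len(k)])
  out$p[is.na(out$p)] <- 1     # constant gene: identical distributions
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[out$p_adj < fdr, , drop = FALSE]
  out[order(out$p_adj, out$p, out$gene), , drop = FALSE]
}
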