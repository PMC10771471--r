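#' Default Gaussian-kernel bandwidth from spot spacing
#'
#' Half of the mean nearest-neighbor distance between spots: the bandwidth
#' at which the mapping performed best across the kernel-parameter sweep.
#'
#' @param y A [spatial_coords()] object with at least two points.
#' @return Positive scalar sigma.
#' @export
default_sigma <- function(y) {
  stopifnot(inherits(y, "SpatialCoords"))
  n <- nrow(y$coords)
  if (n < 2) stop("at least two spots are required to derive sigma")
  d <- as.matrix(stats::dist(y$coords))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  sigma <- 0.5 * mean(nn)
  if (sigma <= 0) {
    stop("duplicate coordinates give sigma = 0; set sigma manually")
  }
  sigma
}

.new_adjacency <- function(weights, kernel, params, row_ids = NULL) {
  if (!is.null(row_ids)) dimnames(weights) <- list(row_ids, row_ids)
  structure(list(weights = weights, kernel = kernel, params = params),
            class = "SpatialAdjacency")
}

#' @export
print.SpatialAdjacency <- function(x, ...) {
  cat(sprintf("SpatialAdjacency (%s kernel): %d x %d\n",
              x$kernel, nrow(x$weights), ncol(x$weights)))
  invisible(x)
}

.row_normalize <- function(w) {
  rs <- rowSums(w)
  if (any(rs <= 0) || any(!is.finite(rs))) {
    stop("adjacency rows must have positive finite sums")
  }
  w / rs
}

#' Row-stochastic spatial adjacency from a Gaussian kernel
#'
#' Kernel weight between spots i and j is
#' `phi_ij = exp(-||Y_i - Y_j||^2 / (2 sigma^2)) / (sqrt(2 pi) sigma)`,
#' including the self pair, after which each row is divided by its sum so
#' that row i is spot i's normalized proximity to all spots.
#'
#' @param y A [spatial_coords()] object.
#' @param sigma Positive bandwidth; defaults to [default_sigma()].
#' @return A `SpatialAdjacency` (row sums 1).
#' @export
gaussian_adjacency <- function(y, sigma = default_sigma(y)) {
  stopifnot(inherits(y, "SpatialCoords"))
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("sigma must be a positive scalar")
  }
  d2 <- as.matrix(stats::dist(y$coords))^2
  phi <- exp(-d2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  .new_adjacency(.row_normalize(phi), "gaussian", list(sigma = sigma),
                 y$row_ids)
}

#' Row-stochastic spatial adjacency from an exponential kernel
#'
#' `phi_ij = exp(-||Y_i - Y_j||_2 / l)`, row-normalized. The scale factor
#' `l` plays the role sigma does for the Gaussian kernel but decays on the
#' distance itself rather than its square, giving heavier tails.
#'
#' @param y A [spatial_coords()] object.
#' @param l Positive scale factor.
#' @return A `SpatialAdjacency`.
#' @export
exponential_adjacency <- function(y, l) {
  stopifnot(inherits(y, "SpatialCoords"))
  if (!is.numeric(l) || length(l) != 1 || l <= 0) {
    stop("scale factor l must be a positive scalar")
  }
  d <- as.matrix(stats::dist(y$coords))
  phi <- exp(-d / l)
  .new_adjacency(.row_normalize(phi), "exponential", list(l = l), y$row_ids)
}

#' Row-stochastic spatial adjacency from k-nearest neighbors
#'
#' Weight 1 for the k nearest other spots (self excluded; ties at the k-th
#' distance broken by spot index), 0 elsewhere, then each row divided by k.
#'
#' @param y A [spatial_coords()] object with N points.
#' @param k Number of neighbors, `1 <= k <= N - 1`.
#' @return A `SpatialAdjacency`.
#' @export
knn_adjacency <- function(y, k) {
  stopifnot(inherits(y, "SpatialCoords"))
  n <- nrow(y$coords)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n - 1) {
    stop("k must satisfy 1 <= k <= N - 1")
  }
  k <- as.integer(k)
  d <- as.matrix(stats::dist(y$coords))
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i]
    w[i, ord[seq_len(k)]] <- 1
  }
  .new_adjacency(w / k, "knn", list(k = k), y$row_ids)
}
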