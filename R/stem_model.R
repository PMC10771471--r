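#' Encoder configuration
#'
#' The shared encoder is a fully connected multilayer perceptron mapping a
#' gene-expression vector of length `n_genes` through `hidden_sizes` ReLU
#' layers to a `latent_dim`-dimensional embedding (no output nonlinearity,
#' biases on). ST inputs additionally pass an input dropout layer with rate
#' `st_dropout_rate` during training, equalizing the sparsity of spot and
#' cell profiles (see [sparsity_dropout_rate()]).
#'
#' @param n_genes Number of input genes H.
#' @param hidden_sizes Integer vector of hidden-layer widths (default 512).
#' @param latent_dim Embedding dimension h (default 128).
#' @param st_dropout_rate Probability d in `[0, 1)` of zeroing an ST input
#'   element during training.
#' @param seed Integer seed; parameter initialization, dropout masks and
#'   mini-batching draw from independent streams derived from it.
#' @return An `EncoderConfig` list.
#' @export
encoder_config <- function(n_genes, hidden_sizes = 512L, latent_dim = 128L,
                           st_dropout_rate = 0, seed = 0L) {
  stopifnot(n_genes >= 1, latent_dim >= 1, all(hidden_sizes >= 1),
            st_dropout_rate >= 0, st_dropout_rate < 1)
  structure(list(n_genes = as.integer(n_genes),
                 hidden_sizes = as.integer(hidden_sizes),
                 latent_dim = as.integer(latent_dim),
                 st_dropout_rate = st_dropout_rate,
                 seed = as.integer(seed)),
            class = "EncoderConfig")
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Independent sub-seeds (init / dropout / batching / misc) from one seed.
.derive_seeds <- function(seed) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, 4L))
}

#' Initialize encoder parameters
#'
#' Standard linear-layer initialization: weights and biases uniform on
#' `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`, which keeps the initial embedding
#' inner products on a moderate scale so the softmax predictors start
#' near-uniform.
#'
#' @param cfg An [encoder_config()].
#' @return A `StemModel`: list with `params` (weight/bias lists) and `cfg`.
#' @export
init_stem_model <- function(cfg) {
  stopifnot(inherits(cfg, "EncoderConfig"))
  sizes <- c(cfg$n_genes, cfg$hidden_sizes, cfg$latent_dim)
  seeds <- .derive_seeds(cfg$seed)
  params <- .with_seed(seeds[1], {
    lapply(seq_len(length(sizes) - 1), function(l) {
      bound <- 1 / sqrt(sizes[l])
      list(W = matrix(stats::runif(sizes[l] * sizes[l + 1], -bound, bound),
                      nrow = sizes[l]),
           b = stats::runif(sizes[l + 1], -bound, bound))
    })
  })
  structure(list(params = params, cfg = cfg, seeds = seeds),
            class = "StemModel")
}

#' @export
print.StemModel <- function(x, ...) {
  sizes <- c(x$cfg$n_genes, x$cfg$hidden_sizes, x$cfg$latent_dim)
  cat(sprintf("StemModel: MLP %s, ST input dropout %.3f\n",
              paste(sizes, collapse = " -> "), x$cfg$st_dropout_rate))
  invisible(x)
}

#' Embeddings container
#' @param vectors n-by-h numeric matrix of latent vectors.
#' @param domain `"SC"` or `"ST"`.
#' @return An `Embeddings` object.
#' @export
embeddings <- function(vectors, domain = c("SC", "ST")) {
  domain <- match.arg(domain)
  vectors <- as.matrix(vectors)
  if (any(!is.finite(vectors))) stop("embeddings must be finite")
  structure(list(vectors = vectors, domain = domain), class = "Embeddings")
}

.embed_mat <- function(z) {
  if (inherits(z, "Embeddings")) z$vectors else as.matrix(z)
}

.expr_mat <- function(x) {
  if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
}

# Forward pass with caches for backprop. `mask` is the (already scaled)
# input dropout mask or NULL.
.mlp_forward <- function(params, x, mask = NULL) {
  xin <- if (is.null(mask)) x else x * mask
  acts <- list()   # post-ReLU activations per hidden layer
  pre <- list()    # pre-activation values per hidden layer
  a <- xin
  n_layers <- length(params)
  for (l in seq_len(n_layers)) {
    h <- sweep(a %*% params[[l]]$W, 2, params[[l]]$b, "+")
    if (l < n_layers) {
      pre[[l]] <- h
      a <- pmax(h, 0)
      acts[[l]] <- a
    } else {
      a <- h
    }
  }
  list(z = a, acts = acts, pre = pre, xin = xin)
}

# Backprop dL/dz through the MLP; returns parameter gradients and dL/dx
# (gradient w.r.t. the *masked* input; multiply by the mask outside if the
# gradient w.r.t. the raw input is needed).
.mlp_backward <- function(params, cache, dz) {
  n_layers <- length(params)
  grads <- vector("list", n_layers)
  d <- dz
  for (l in rev(seq_len(n_layers))) {
    a_prev <- if (l == 1) cache$xin else cache$acts[[l - 1]]
    grads[[l]] <- list(W = crossprod(a_prev, d), b = colSums(d))
    d <- d %*% t(params[[l]]$W)
    if (l > 1) d <- d * (cache$pre[[l - 1]] > 0)
  }
  list(grads = grads, dx = d)
}

#' Encode expression profiles into the latent space
#'
#' @param model A [init_stem_model()] (or trained) `StemModel`.
#' @param x An [expression_matrix()] (lognorm layer) or numeric matrix with
#'   genes in the model's input order.
#' @param domain `"SC"` or `"ST"`; tags the output.
#' @param training Apply the ST input dropout layer (only meaningful for
#'   ST data; ignored when the configured rate is 0).
#' @param dropout_seed Optional seed making the dropout mask reproducible.
#' @return An [embeddings()] object (n-by-h).
#' @export
encode <- function(model, x, domain = c("SC", "ST"), training = FALSE,
                   dropout_seed = NULL) {
  stopifnot(inherits(model, "StemModel"))
  domain <- match.arg(domain)
  xm <- .expr_mat(x)
  if (ncol(xm) != model$cfg$n_genes) {
    stop(sprintf("input has %d genes but the model expects %d",
                 ncol(xm), model$cfg$n_genes))
  }
  mask <- NULL
  d <- model$cfg$st_dropout_rate
  if (training && domain == "ST" && d > 0) {
    draw <- function() {
      matrix(stats::rbinom(length(xm), 1, 1 - d) / (1 - d), nrow = nrow(xm))
    }
    mask <- if (is.null(dropout_seed)) draw() else .with_seed(dropout_seed, draw())
  }
  embeddings(.mlp_forward(model$params, xm, mask)$z, domain)
}

#' ST input dropout rate from relative sparsity
#'
#' A spot aggregates several cells, so spots express more genes than cells.
#' The rate `d = 1 - median(genes detected per cell) / median(genes
#' detected per spot)` zeroes ST inputs during training until both domains
#' show the same sparsity level. Clamped to `[0, 0.95]`; a clamp at 0
#' (SC denser than ST) warns.
#'
#' @param sc,st Raw-count [expression_matrix()] objects.
#' @return Scalar dropout rate in `[0, 0.95]`.
#' @export
sparsity_dropout_rate <- function(sc, st) {
  scm <- .expr_mat(sc); stm <- .expr_mat(st)
  med_sc <- stats::median(rowSums(scm > 0))
  med_st <- stats::median(rowSums(stm > 0))
  if (med_sc == 0 || med_st == 0) {
    stop("cannot derive a dropout rate from all-zero expression rows")
  }
  d <- 1 - med_sc / med_st
  if (d < 0) {
    warning("SC data denser than ST data; dropout rate clamped to 0")
    d <- 0
  }
  min(d, 0.95)
}

# Numerically stable row softmax.
.row_softmax <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# Row log-softmax; entries stay finite even when the softmax underflows.
.row_log_softmax <- function(m) {
  shifted <- m - apply(m, 1, max)
  shifted - log(rowSums(exp(shifted)))
}

#' Predicted intra-ST spatial adjacency from ST embeddings
#'
#' `S~_ij = exp(<Z_i, Z_j>) / sum_k exp(<Z_i, Z_k>)`: a row softmax over
#' pairwise inner products, so row i is a distribution over spots.
#'
#' @param z_st ST [embeddings()] (or matrix), at least 2 rows.
#' @return N-by-N row-stochastic matrix.
#' @export
intra_adjacency <- function(z_st) {
  z <- .embed_mat(z_st)
  if (nrow(z) < 2) stop("at least two spots are required")
  .row_softmax(tcrossprod(z))
}

#' Cross-domain mapping matrices from SC and ST embeddings
#'
#' With similarity `B_ij = <Z^SC_i, Z^ST_j>`, the SC-to-ST mapping is
#' `C = rowsoftmax(B)` (each cell's distribution over spots) and the
#' ST-to-SC mapping is `C^ = rowsoftmax(B^T)` (each spot's distribution
#' over cells).
#'
#' @param z_sc,z_st [embeddings()] (or matrices) with equal latent
#'   dimension.
#' @return List with row-stochastic `C` (M-by-N) and `Chat` (N-by-M).
#' @export
cross_mapping <- function(z_sc, z_st) {
  zs <- .embed_mat(z_sc); zt <- .embed_mat(z_st)
  if (ncol(zs) != ncol(zt)) stop("latent dimensions differ")
  b <- tcrossprod(zs, zt)
  list(C = .row_softmax(b), Chat = .row_softmax(t(b)))
}

#' Two-step ST spatial adjacency through the SC domain
#'
#' `S^ = C^ %*% C`: spot -> cells -> spots. A product of row-stochastic
#' matrices, hence row-stochastic.
#'
#' @param c_mat M-by-N row-stochastic SC-to-ST mapping.
#' @param chat_mat N-by-M row-stochastic ST-to-SC mapping.
#' @return N-by-N row-stochastic matrix.
#' @export
two_step_adjacency <- function(c_mat, chat_mat) {
  if (ncol(chat_mat) != nrow(c_mat)) stop("mapping matrix shapes mismatch")
  chat_mat %*% c_mat
}

#' Mean row-wise cross entropy between a prediction and the truth
#'
#' `H_i = -sum_j truth_ij log(pred_ij)`, averaged over rows. Both arguments
#' are row-stochastic; predictions must be strictly positive (softmax
#' outputs are).
#'
#' @param pred Row-stochastic prediction matrix (entries > 0).
#' @param truth A `SpatialAdjacency` or row-stochastic matrix of the same
#'   shape.
#' @return Non-negative scalar loss.
#' @export
row_cross_entropy <- function(pred, truth) {
  t_mat <- if (inherits(truth, "SpatialAdjacency")) truth$weights else truth
  pred <- as.matrix(pred)
  if (!all(dim(pred) == dim(t_mat))) stop("shape mismatch")
  if (any(pred <= 0)) stop("prediction entries must be strictly positive")
  -mean(rowSums(t_mat * log(pred)))
}

# Pairwise squared Euclidean distances between rows of a and rows of b.
.sqdist <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

.mmd_bandwidths <- function(a, b, multipliers = c(0.5, 1, 2)) {
  pooled <- rbind(a, b)
  d <- sqrt(.sqdist(pooled, pooled))
  med <- stats::median(d[upper.tri(d)])
  if (!is.finite(med) || med <= 0) med <- 1
  multipliers * med
}

#' Maximum mean discrepancy between two embedding batches
#'
#' Kernel two-sample statistic (squared MMD) measuring how far apart the SC
#' and ST embedding distributions are. The default kernel is a sum of
#' Gaussian RBF kernels `exp(-||x-y||^2 / (2 bw^2))` at bandwidths
#' `{0.5, 1, 2}` times the median pairwise distance of the pooled batch.
#' The default estimator is unbiased: for equal batch sizes the paired
#' U-statistic (exactly 0 on identical batches), otherwise the general
#' U-statistic with the diagonal excluded from the within-batch terms. The
#' `"biased"` V-statistic keeps all pairs and is always non-negative; with
#' `kernel = "linear"` it equals `||mean(a) - mean(b)||^2`.
#'
#' @param z_a,z_b Batches ([embeddings()] or matrices), each with at least
#'   2 rows.
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param estimator `"unbiased"` (default) or `"biased"`.
#' @param bandwidth_multipliers RBF bandwidth multipliers of the median
#'   pooled pairwise distance.
#' @return Scalar squared-MMD estimate (unbiased estimates may be slightly
#'   negative).
#' @export
mmd <- function(z_a, z_b, kernel = c("rbf", "linear"),
                estimator = c("unbiased", "biased"),
                bandwidth_multipliers = c(0.5, 1, 2)) {
  kernel <- match.arg(kernel); estimator <- match.arg(estimator)
  a <- .embed_mat(z_a); b <- .embed_mat(z_b)
  m <- nrow(a); n <- nrow(b)
  if (m < 2 || n < 2) stop("each batch needs at least two rows")
  if (kernel == "linear") {
    kaa <- tcrossprod(a); kbb <- tcrossprod(b); kab <- tcrossprod(a, b)
  } else {
    bw <- .mmd_bandwidths(a, b, bandwidth_multipliers)
    rbf <- function(d2) Reduce(`+`, lapply(bw, function(s) exp(-d2 / (2 * s^2))))
    kaa <- rbf(.sqdist(a, a)); kbb <- rbf(.sqdist(b, b))
    kab <- rbf(.sqdist(a, b))
  }
  if (estimator == "biased") {
    return(mean(kaa) + mean(kbb) - 2 * mean(kab))
  }
  if (m == n) {
    # paired U-statistic: exactly zero when the batches coincide
    off <- !diag(TRUE, m)
    sum((kaa + kbb - kab - t(kab))[off]) / (m * (m - 1))
  } else {
    sum(kaa[!diag(TRUE, m)]) / (m * (m - 1)) +
      sum(kbb[!diag(TRUE, n)]) / (n * (n - 1)) -
      2 * mean(kab)
  }
}

# Gradient of the general unbiased MMD^2 (multi-RBF kernel, fixed
# bandwidths) w.r.t. both batches. Used by the training loop.
.mmd_grad <- function(a, b, bandwidths) {
  m <- nrow(a); n <- nrow(b)
  kmats <- function(x, y) {
    d2 <- .sqdist(x, y)
    # sum over bandwidths of k_s(x,y)/s^2 enters the gradient
    k <- 0; kg <- 0
    for (s in bandwidths) {
      ks <- exp(-d2 / (2 * s^2))
      k <- k + ks
      kg <- kg + ks / s^2
    }
    list(k = k, kg = kg)
  }
  aa <- kmats(a, a); bb <- kmats(b, b); ab <- kmats(a, b)
  value <- sum(aa$k[!diag(TRUE, m)]) / (m * (m - 1)) +
    sum(bb$k[!diag(TRUE, n)]) / (n * (n - 1)) -
    2 * mean(ab$k)
  # d/dx_i of c * sum_ij w_ij k(x_i, y_j) with k RBF:
  #   c * sum_j w_ij kg_ij (y_j - x_i)
  grad_from <- function(w_kg, x, y, coef) {
    coef * (w_kg %*% y - rowSums(w_kg) * x)
  }
  kg_aa <- aa$kg; diag(kg_aa) <- 0
  kg_bb <- bb$kg; diag(kg_bb) <- 0
  # within-a term: both index positions contribute -> factor 2
  da <- grad_from(kg_aa, a, a, 2 / (m * (m - 1))) -
    grad_from(ab$kg, a, b, 2 / (m * n))
  db <- grad_from(kg_bb, b, b, 2 / (n * (n - 1))) -
    grad_from(t(ab$kg), b, a, 2 / (m * n))
  list(value = value, da = da, db = db)
}

#' Combine the three loss terms into a loss record
#'
#' `total = l_extract + alpha * l_mmd + beta * l_trans`. `alpha` defaults
#' to 0.5, the shipped default weight of the MMD term; `beta` is scheduled
#' from 0 to 1 during training (see [beta_schedule()]).
#'
#' @param l_extract Intra-ST adjacency cross-entropy (>= 0).
#' @param l_mmd MMD term (unbiased estimates may be slightly negative).
#' @param l_trans Two-step adjacency cross-entropy (>= 0).
#' @param alpha Weight of the MMD term, >= 0.
#' @param beta Weight of the transfer term in `[0, 1]`.
#' @return A `LossRecord` list with the components and `total`.
#' @export
total_loss <- function(l_extract, l_mmd, l_trans, alpha = 0.5, beta = 1) {
  stopifnot(alpha >= 0, beta >= 0, beta <= 1)
  structure(list(l_extract = l_extract, l_mmd = l_mmd, l_trans = l_trans,
                 alpha = alpha, beta = beta,
                 total = l_extract + alpha * l_mmd + beta * l_trans),
            class = "LossRecord")
}

#' @export
print.LossRecord <- function(x, ...) {
  cat(sprintf(
    "LossRecord: total %.4f (extract %.4f + %.2f * mmd %.4f + %.2f * trans %.4f)\n",
    x$total, x$l_extract, x$alpha, x$l_mmd, x$beta, x$l_trans))
  invisible(x)
}
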