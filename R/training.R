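#' Training configuration
#'
#' @param alpha Weight of the MMD loss term (default 0.5).
#' @param epochs Number of epochs (default 400).
#' @param batch_size_sc,batch_size_st Mini-batch sizes; default
#'   `min(1024, M)` and `min(512, N)`.
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed Seed controlling batching and dropout masks.
#' @param beta_schedule `"linear"` (0 to 1 across epochs, default) or
#'   `"constant"` (1 throughout).
#' @param verbose Print the loss every 50 epochs.
#' @return A `TrainConfig` list.
#' @export
train_config <- function(alpha = 0.5, epochs = 400L, batch_size_sc = NULL,
                         batch_size_st = NULL, learning_rate = 1e-3,
                         seed = 0L, beta_schedule = c("linear", "constant"),
                         verbose = FALSE) {
  beta_schedule <- match.arg(beta_schedule)
  stopifnot(alpha >= 0, epochs >= 1, learning_rate > 0)
  structure(list(alpha = alpha, epochs = as.integer(epochs),
                 batch_size_sc = batch_size_sc, batch_size_st = batch_size_st,
                 learning_rate = learning_rate, seed = as.integer(seed),
                 beta_schedule = beta_schedule, verbose = verbose),
            class = "TrainConfig")
}

#' Weight schedule for the transfer loss
#'
#' The transfer term is ramped in linearly, `beta = epoch / (epochs - 1)`,
#' so the model first learns to reconstruct the intra-ST spatial adjacency
#' and only then the cross-domain mapping. `"constant"` keeps beta = 1.
#'
#' @param epoch Zero-based epoch index, `0 <= epoch < total_epochs`.
#' @param total_epochs Total number of epochs.
#' @param kind `"linear"` or `"constant"`.
#' @return Scalar beta in `[0, 1]`.
#' @export
beta_schedule <- function(epoch, total_epochs, kind = c("linear", "constant")) {
  kind <- match.arg(kind)
  if (epoch < 0 || epoch >= total_epochs) {
    stop("epoch must satisfy 0 <= epoch < total_epochs")
  }
  if (kind == "constant" || total_epochs < 2) return(1)
  epoch / (total_epochs - 1)
}

# Renormalize the rows of a truth sub-matrix so each stays a distribution.
.renorm_rows <- function(m) m / rowSums(m)

.adam_init <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

.adam_step <- function(params, grads, state, lr, t,
                       b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (l in seq_along(params)) {
    g <- grads[[l]]
    s <- state[[l]]
    s$mW <- b1 * s$mW + (1 - b1) * g$W
    s$vW <- b2 * s$vW + (1 - b2) * g$W^2
    s$mb <- b1 * s$mb + (1 - b1) * g$b
    s$vb <- b2 * s$vb + (1 - b2) * g$b^2
    mW_hat <- s$mW / (1 - b1^t); vW_hat <- s$vW / (1 - b2^t)
    mb_hat <- s$mb / (1 - b1^t); vb_hat <- s$vb / (1 - b2^t)
    params[[l]]$W <- params[[l]]$W - lr * mW_hat / (sqrt(vW_hat) + eps)
    params[[l]]$b <- params[[l]]$b - lr * mb_hat / (sqrt(vb_hat) + eps)
    state[[l]] <- s
  }
  list(params = params, state = state)
}

# One forward/backward pass on a mini-batch; returns the three loss terms
# and the parameter gradients (summed over the SC and ST passes).
.stem_step <- function(params, x_sc, x_st, s_b, alpha, beta, mask) {
  fw_st <- .mlp_forward(params, x_st, mask)
  fw_sc <- .mlp_forward(params, x_sc, NULL)
  zt <- fw_st$z; zs <- fw_sc$z
  nt <- nrow(zt)

  # extraction loss: row softmax of ST inner products vs truth
  # (log-softmax form: finite even where the softmax underflows)
  a_mat <- tcrossprod(zt)
  p_tilde <- .row_softmax(a_mat)
  l_extract <- -mean(rowSums(s_b * .row_log_softmax(a_mat)))
  d_a <- (p_tilde - s_b) / nt
  d_zt <- (d_a + t(d_a)) %*% zt

  # transfer loss: two-step adjacency through the SC domain
  b_mat <- tcrossprod(zs, zt)
  c_mat <- .row_softmax(b_mat)
  ch_mat <- .row_softmax(t(b_mat))
  s_hat <- pmax(ch_mat %*% c_mat, .Machine$double.xmin)
  l_trans <- -mean(rowSums(s_b * log(s_hat)))
  d_shat <- -(s_b / s_hat) / nt
  d_c <- crossprod(ch_mat, d_shat)
  d_ch <- tcrossprod(d_shat, c_mat)
  d_b <- c_mat * (d_c - rowSums(d_c * c_mat))
  d_bt <- ch_mat * (d_ch - rowSums(d_ch * ch_mat))
  d_b <- d_b + t(d_bt)
  d_zs <- beta * (d_b %*% zt)
  d_zt <- d_zt + beta * crossprod(d_b, zs)

  # MMD between the two embedding batches (bandwidths held fixed)
  bw <- .mmd_bandwidths(zs, zt)
  mg <- .mmd_grad(zs, zt, bw)
  l_mmd <- mg$value
  d_zs <- d_zs + alpha * mg$da
  d_zt <- d_zt + alpha * mg$db

  bk_st <- .mlp_backward(params, fw_st, d_zt)
  bk_sc <- .mlp_backward(params, fw_sc, d_zs)
  grads <- lapply(seq_along(params), function(l) {
    list(W = bk_st$grads[[l]]$W + bk_sc$grads[[l]]$W,
         b = bk_st$grads[[l]]$b + bk_sc$grads[[l]]$b)
  })
  list(l_extract = l_extract, l_mmd = l_mmd, l_trans = l_trans,
       grads = grads)
}

#' Train the shared encoder on aligned SC and ST expression
#'
#' Optimizes `L = L_extract + alpha * L_MMD + beta * L_trans` with Adam.
#' `L_extract` is the cross entropy between the softmaxed ST embedding
#' inner products and the ground-truth spatial adjacency; `L_trans` applies
#' the same loss to the two-step adjacency built from the SC-ST and ST-SC
#' mapping matrices; `L_MMD` aligns the two embedding distributions. Each
#' step samples an ST and an SC mini-batch (without replacement within an
#' epoch); the truth rows are restricted to the ST batch and renormalized.
#' beta follows [beta_schedule()]; alpha stays constant.
#'
#' @param sc,st Log-normalized [expression_matrix()] objects with identical
#'   gene order (see [align_genes()]).
#' @param s_truth A `SpatialAdjacency` whose dimension equals the number of
#'   ST rows.
#' @param enc_cfg An [encoder_config()]; its `n_genes` must match the
#'   aligned gene count.
#' @param cfg A [train_config()].
#' @return A `StemFit` list: `model` (trained `StemModel`), `z_sc`, `z_st`
#'   (final [embeddings()] computed without dropout), and `history`
#'   (data.frame of per-epoch loss components).
#' @export
train_stem <- function(sc, st, s_truth, enc_cfg, cfg = train_config()) {
  stopifnot(inherits(enc_cfg, "EncoderConfig"), inherits(cfg, "TrainConfig"))
  x_sc <- .expr_mat(sc); x_st <- .expr_mat(st)
  if (!is.null(attr(sc, "class")) && inherits(sc, "ExpressionMatrix") &&
      inherits(st, "ExpressionMatrix") &&
      !identical(sc$gene_ids, st$gene_ids)) {
    stop("SC and ST gene ids are not aligned; run align_genes() first")
  }
  if (ncol(x_sc) != enc_cfg$n_genes) {
    stop("encoder n_genes does not match the aligned gene count")
  }
  s_mat <- if (inherits(s_truth, "SpatialAdjacency")) s_truth$weights else s_truth
  n <- nrow(x_st); m <- nrow(x_sc)
  if (nrow(s_mat) != n || ncol(s_mat) != n) {
    stop("s_truth dimension must equal the number of ST rows")
  }

  bs_sc <- if (is.null(cfg$batch_size_sc)) min(1024L, m) else min(cfg$batch_size_sc, m)
  bs_st <- if (is.null(cfg$batch_size_st)) min(512L, n) else min(cfg$batch_size_st, n)
  if (bs_sc < 2 || bs_st < 2) stop("batch sizes must be at least 2")

  model <- init_stem_model(enc_cfg)
  params <- model$params
  adam <- .adam_init(params)
  seeds <- .derive_seeds(cfg$seed)
  d_rate <- enc_cfg$st_dropout_rate
  t_step <- 0L

  history <- data.frame(epoch = seq_len(cfg$epochs) - 1L, l_extract = NA_real_,
                        l_mmd = NA_real_, l_trans = NA_real_,
                        alpha = cfg$alpha, beta = NA_real_, total = NA_real_)

  for (epoch in seq_len(cfg$epochs) - 1L) {
    beta <- beta_schedule(epoch, cfg$epochs, cfg$beta_schedule)
    plan <- .with_seed((seeds[3] + epoch) %% .Machine$integer.max, {
      list(sc = sample.int(m), st = sample.int(n))
    })
    sc_batches <- split(plan$sc, ceiling(seq_len(m) / bs_sc))
    st_batches <- split(plan$st, ceiling(seq_len(n) / bs_st))
    # drop runt batches smaller than 2 (softmax over a single row is fine
    # but MMD needs >= 2)
    sc_batches <- Filter(function(b) length(b) >= 2, sc_batches)
    st_batches <- Filter(function(b) length(b) >= 2, st_batches)
    n_steps <- max(length(sc_batches), length(st_batches))
    acc <- c(l_extract = 0, l_mmd = 0, l_trans = 0)
    for (s in seq_len(n_steps)) {
      sc_idx <- sc_batches[[(s - 1L) %% length(sc_batches) + 1L]]
      st_idx <- st_batches[[(s - 1L) %% length(st_batches) + 1L]]
      s_b <- .renorm_rows(s_mat[st_idx, st_idx, drop = FALSE])
      mask <- NULL
      if (d_rate > 0) {
        mask_seed <- (seeds[2] + epoch * 131L + s) %% .Machine$integer.max
        mask <- .with_seed(mask_seed, {
          matrix(stats::rbinom(length(st_idx) * enc_cfg$n_genes, 1,
                               1 - d_rate) / (1 - d_rate),
                 nrow = length(st_idx))
        })
      }
      step <- .stem_step(params, x_sc[sc_idx, , drop = FALSE],
                         x_st[st_idx, , drop = FALSE], s_b,
                         cfg$alpha, beta, mask)
      terms <- c(l_extract = step$l_extract, l_mmd = step$l_mmd,
                 l_trans = step$l_trans)
      if (any(!is.finite(terms))) {
        bad <- names(terms)[!is.finite(terms)][1]
        stop(sprintf("non-finite loss term '%s' at epoch %d", bad, epoch))
      }
      acc <- acc + terms
      t_step <- t_step + 1L
      upd <- .adam_step(params, step$grads, adam, cfg$learning_rate, t_step)
      params <- upd$params; adam <- upd$state
    }
    acc <- acc / n_steps
    history[epoch + 1L, c("l_extract", "l_mmd", "l_trans")] <- acc
    history$beta[epoch + 1L] <- beta
    history$total[epoch + 1L] <-
      acc["l_extract"] + cfg$alpha * acc["l_mmd"] + beta * acc["l_trans"]
    if (cfg$verbose && (epoch %% 50 == 0 || epoch == cfg$epochs - 1)) {
      message(sprintf("epoch %4d  extract %.4f  mmd %.4f  trans %.4f  beta %.2f",
                      epoch, acc["l_extract"], acc["l_mmd"], acc["l_trans"], beta))
    }
  }

  model$params <- params
  z_sc <- encode(model, x_sc, domain = "SC", training = FALSE)
  z_st <- encode(model, x_st, domain = "ST", training = FALSE)
  structure(list(model = model, z_sc = z_sc, z_st = z_st, history = history),
            class = "StemFit")
}

#' @export
print.StemFit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("StemFit: %d epochs, final total loss %.4f (extract %.4f, trans %.4f)\n",
              nrow(x$history), last$total, last$l_extract, last$l_trans))
  invisible(x)
}
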