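test_that("sparsity dropout rate follows the median ratio with clamping", {
  # medians 1000 (SC) vs 4000 (ST) -> d = 0.75
  sc <- matrix(0, 3, 5000); sc[, 1:1000] <- 1
  st <- matrix(0, 3, 5000); st[, 1:4000] <- 1
  expect_equal(sparsity_dropout_rate(sc, st), 0.75)
  expect_equal(sparsity_dropout_rate(sc, sc), 0)
  expect_warning(d <- sparsity_dropout_rate(st, sc), "clamped")
  expect_equal(d, 0)
  expect_error(sparsity_dropout_rate(matrix(0, 2, 3), st), "all-zero")
})

test_that("encoding is deterministic in eval mode and reproducibly masked in training", {
  cfg <- encoder_config(6, hidden_sizes = 8, latent_dim = 4,
                        st_dropout_rate = 0.5, seed = 1)
  model <- init_stem_model(cfg)
  x <- matrix(runif(12), 2, 6)
  z1 <- encode(model, x)
  z2 <- encode(model, x)
  expect_identical(z1$vectors, z2$vectors)
  expect_true(all(is.finite(z1$vectors)))
  # identical input rows give identical embeddings
  xx <- rbind(x[1, ], x[1, ])
  zz <- encode(model, xx)
  expect_equal(zz$vectors[1, ], zz$vectors[2, ])
  # seeded dropout masks reproduce exactly
  za <- encode(model, x, domain = "ST", training = TRUE, dropout_seed = 42)
  zb <- encode(model, x, domain = "ST", training = TRUE, dropout_seed = 42)
  expect_identical(za$vectors, zb$vectors)
  expect_error(encode(model, matrix(1, 2, 5)), "expects 6|genes")
})

test_that("intra-ST adjacency is the row softmax of embedding inner products", {
  # all-zero embeddings -> uniform rows
  z0 <- matrix(0, 4, 3)
  expect_equal(intra_adjacency(z0), matrix(0.25, 4, 4))

  # two orthonormal embeddings: self entry e/(e+1)
  z <- rbind(c(1, 0), c(0, 1))
  s <- intra_adjacency(z)
  expect_equal(s[1, ], c(exp(1), 1) / (exp(1) + 1))

  # brute-force softmax oracle
  set.seed(10)
  z6 <- matrix(rnorm(6 * 5), 6, 5)
  g <- z6 %*% t(z6)
  oracle <- t(apply(g, 1, function(r) exp(r) / sum(exp(r))))
  expect_equal(intra_adjacency(z6), oracle, tolerance = 1e-10)

  # numerically stable at large inner products
  big <- matrix(c(30, 0, 0, 30), 2, 2) # |<z,z>| = 900
  expect_true(all(is.finite(intra_adjacency(big))))
})

test_that("cross mapping produces row-stochastic matrices in both directions", {
  z0s <- matrix(0, 4, 3); z0t <- matrix(0, 5, 3)
  cm0 <- cross_mapping(z0s, z0t)
  expect_equal(cm0$C, matrix(1 / 5, 4, 5))
  expect_equal(cm0$Chat, matrix(1 / 4, 5, 4))

  # a cell coinciding with an ST embedding maps preferentially to it
  zt <- diag(3)
  zs <- matrix(zt[2, ], 1, 3)
  cm <- cross_mapping(zs, zt)
  expect_equal(which.max(cm$C[1, ]), 2L)

  # brute-force oracle
  set.seed(11)
  zs4 <- matrix(rnorm(4 * 3), 4, 3); zt5 <- matrix(rnorm(5 * 3), 5, 3)
  b <- zs4 %*% t(zt5)
  or_c <- t(apply(b, 1, function(r) exp(r) / sum(exp(r))))
  or_ch <- t(apply(t(b), 1, function(r) exp(r) / sum(exp(r))))
  cm2 <- cross_mapping(zs4, zt5)
  expect_equal(cm2$C, or_c, tolerance = 1e-10)
  expect_equal(cm2$Chat, or_ch, tolerance = 1e-10)
  expect_error(cross_mapping(zs4, matrix(1, 2, 4)), "latent")
})

test_that("permuting SC rows permutes C rows and Chat columns identically", {
  set.seed(12)
  zs <- matrix(rnorm(6 * 4), 6, 4); zt <- matrix(rnorm(5 * 4), 5, 4)
  perm <- sample(6)
  cm <- cross_mapping(zs, zt)
  cmp <- cross_mapping(zs[perm, ], zt)
  expect_equal(cmp$C, cm$C[perm, ], tolerance = 1e-12)
  expect_equal(cmp$Chat, cm$Chat[, perm], tolerance = 1e-12)
})

test_that("two-step adjacency is the product and stays row-stochastic", {
  u <- matrix(1 / 4, 3, 4); v <- matrix(1 / 3, 4, 3)
  expect_equal(two_step_adjacency(u, v), matrix(1 / 4, 4, 4))

  # permutation-like one-hot mappings compose to the identity
  p <- diag(3)[c(2, 3, 1), ]
  expect_equal(two_step_adjacency(t(p), p), diag(3))

  set.seed(13)
  c_mat <- rand_stochastic(3, 4); ch <- rand_stochastic(4, 3)
  s_hat <- two_step_adjacency(c_mat, ch)
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) oracle[i, j] <- sum(ch[i, ] * c_mat[, j])
  expect_equal(s_hat, oracle, tolerance = 1e-12)
  expect_equal(rowSums(s_hat), rep(1, 4), tolerance = 1e-12)
  expect_error(two_step_adjacency(c_mat, rand_stochastic(4, 4)), "mismatch")
})

test_that("row cross entropy equals log N for uniform predictions and obeys Gibbs", {
  set.seed(14)
  n <- 8
  truth <- rand_stochastic(n)
  unif <- matrix(1 / n, n, n)
  expect_equal(row_cross_entropy(unif, truth), log(n), tolerance = 1e-12)

  self_loss <- row_cross_entropy(truth, truth)
  for (rep in 1:50) {
    p <- rand_stochastic(n)
    expect_gte(row_cross_entropy(p, truth), self_loss)
  }
  expect_error(row_cross_entropy(truth * 0, truth), "positive")
})

test_that("mmd vanishes on identical batches and detects separated ones", {
  set.seed(15)
  a <- matrix(rnorm(20 * 4), 20, 4)
  expect_lt(abs(mmd(a, a)), 1e-9)

  # linear-kernel V-statistic equals the squared mean difference (closed form)
  za <- matrix(c(1, 0, 0, 1, 2, 1), 3, 2)
  zb <- matrix(c(0, 1, 1, 3, 0, 2), 3, 2)
  expect_equal(mmd(za, zb, kernel = "linear", estimator = "biased"),
               sum((colMeans(za) - colMeans(zb))^2), tolerance = 1e-12)

  # separation: N(0,I) vs N(5,I) far exceeds the same-distribution value
  p1 <- matrix(rnorm(100 * 4), 100, 4)
  p2 <- matrix(rnorm(100 * 4), 100, 4)
  q <- matrix(rnorm(100 * 4, mean = 5), 100, 4)
  expect_gt(mmd(p1, q), mmd(p1, p2))
  expect_gt(mmd(p1, q), 0.5)
  expect_error(mmd(a[1, , drop = FALSE], a), "at least two")
})

test_that("mmd is symmetric and translation invariant", {
  set.seed(16)
  a <- matrix(rnorm(15 * 3), 15, 3)
  b <- matrix(rnorm(12 * 3), 12, 3)
  expect_equal(mmd(a, b), mmd(b, a), tolerance = 1e-12)
  shift <- matrix(rep(c(3, -2, 7), each = 1), 1, 3)
  expect_equal(mmd(a + shift[rep(1, 15), ], b + shift[rep(1, 12), ]),
               mmd(a, b), tolerance = 1e-9)
})

test_that("total loss combines the three terms with alpha and beta", {
  lr <- total_loss(1.0, 0.2, 0.5, alpha = 0.5, beta = 1)
  expect_equal(lr$total, 1.6)
  expect_equal(total_loss(1.0, 0.2, 0.5, alpha = 0.5, beta = 0)$total,
               total_loss(1.0, 0.2, 99, alpha = 0.5, beta = 0)$total)
  expect_equal(formals(total_loss)$alpha, 0.5)
  expect_equal(lr$total, lr$l_extract + lr$alpha * lr$l_mmd + lr$beta * lr$l_trans)
})

test_that("backprop gradients match finite differences", {
  set.seed(17)
  cfg <- encoder_config(7, hidden_sizes = 5, latent_dim = 3, seed = 3)
  params <- init_stem_model(cfg)$params
  x_sc <- matrix(runif(6 * 7), 6, 7)
  x_st <- matrix(runif(5 * 7), 5, 7)
  s_b <- matrix(runif(25), 5, 5); s_b <- s_b / rowSums(s_b)
  beta <- 0.6
  loss_fn <- function(p) {
    st <- spatem:::.stem_step(p, x_sc, x_st, s_b, 0, beta, NULL)
    st$l_extract + beta * st$l_trans
  }
  step <- spatem:::.stem_step(params, x_sc, x_st, s_b, 0, beta, NULL)
  eps <- 1e-6
  for (l in 1:2) {
    g <- step$grads[[l]]$W
    for (i in sample(length(g), 8)) {
      pp <- params; pp[[l]]$W[i] <- pp[[l]]$W[i] + eps
      pm <- params; pm[[l]]$W[i] <- pm[[l]]$W[i] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
  # MMD gradient against finite differences at fixed bandwidths
  a <- matrix(rnorm(12), 4, 3); b <- matrix(rnorm(15), 5, 3)
  bw <- c(0.8, 1.3)
  mg <- spatem:::.mmd_grad(a, b, bw)
  val_fn <- function(a, b) {
    rbf <- function(d2) exp(-d2 / (2 * bw[1]^2)) + exp(-d2 / (2 * bw[2]^2))
    kaa <- rbf(as.matrix(dist(a))^2); kbb <- rbf(as.matrix(dist(b))^2)
    kab <- rbf(spatem:::.sqdist(a, b))
    sum(kaa[!diag(TRUE, 4)]) / 12 + sum(kbb[!diag(TRUE, 5)]) / 20 -
      2 * mean(kab)
  }
  expect_equal(mg$value, val_fn(a, b), tolerance = 1e-12)
  for (i in sample(length(a), 5)) {
    ap <- a; ap[i] <- ap[i] + eps
    am <- a; am[i] <- am[i] - eps
    expect_equal(mg$da[i], (val_fn(ap, b) - val_fn(am, b)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("predictor outputs are row-stochastic for arbitrary finite embeddings", {
  set.seed(18)
  for (rep in 1:10) {
    zs <- matrix(rnorm(7 * 4, sd = 3), 7, 4)
    zt <- matrix(rnorm(6 * 4, sd = 3), 6, 4)
    cm <- cross_mapping(zs, zt)
    s_tilde <- intra_adjacency(zt)
    s_hat <- two_step_adjacency(cm$C, cm$Chat)
    for (m in list(s_tilde, cm$C, cm$Chat, s_hat)) {
      expect_true(all(abs(rowSums(m) - 1) < 1e-8))
      expect_true(all(m >= 0))
    }
  }
})
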