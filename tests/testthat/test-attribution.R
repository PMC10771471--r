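test_that("integrated gradients are exact for linear functions and zero at baseline", {
  set.seed(30)
  w <- rnorm(6)
  f <- function(v) sum(w * v)
  x <- runif(6)
  for (steps in c(1, 3, 50)) {
    ig <- integrated_gradients(x, f, steps = steps)
    expect_equal(ig$attribution, x * w, tolerance = 1e-8)
    expect_lt(ig$convergence_gap, 1e-10)
  }
  ig0 <- integrated_gradients(rep(0, 6), f, steps = 10)
  expect_equal(ig0$attribution, rep(0, 6))
})

test_that("attribution completeness gap shrinks with step refinement on a trained model", {
  fx <- tiny_trained_fit()
  x <- fx$sc_norm$values
  params <- fx$fit$model$params
  z_st <- fx$fit$z_st$vectors
  # pick the cell with the most confident mapping
  p <- spatem:::.row_softmax(tcrossprod(
    spatem:::.mlp_forward(params, x, NULL)$z, z_st))
  i <- which.max(apply(p, 1, max))
  m_idx <- which.max(p[i, ])
  f <- function(v) {
    spatem:::.map_prob_forward(params, matrix(v, 1), z_st, m_idx)$f
  }
  grad_f <- function(v) {
    drop(spatem:::.map_prob_grad(params, matrix(v, 1), z_st, m_idx)$dx)
  }
  delta <- abs(f(x[i, ]) - f(0 * x[i, ]))
  gaps <- vapply(c(8, 32, 128, 256), function(s) {
    integrated_gradients(x[i, ], f, steps = s, grad_f = grad_f)$convergence_gap
  }, numeric(1))
  expect_lt(gaps[4], gaps[1])
  expect_lt(gaps[4], 0.01 * delta)
})

test_that("analytic attribution matches a finite-difference path integral", {
  fx <- tiny_trained_fit()
  params <- fx$fit$model$params
  z_st <- fx$fit$z_st$vectors
  x <- fx$sc_norm$values[3, ]
  zsc <- spatem:::.mlp_forward(params, matrix(x, 1), NULL)$z
  m_idx <- which.max(tcrossprod(zsc, z_st))
  f <- function(v) {
    spatem:::.map_prob_forward(params, matrix(v, 1), z_st, m_idx)$f
  }
  grad_f <- function(v) {
    drop(spatem:::.map_prob_grad(params, matrix(v, 1), z_st, m_idx)$dx)
  }
  analytic <- integrated_gradients(x, f, steps = 20, grad_f = grad_f)
  numeric_ig <- integrated_gradients(x, f, steps = 20)  # finite differences
  expect_equal(unname(analytic$attribution), unname(numeric_ig$attribution),
               tolerance = 1e-3)
})

test_that("attribution profiles are deterministic and zero for silent genes", {
  fx <- tiny_trained_fit()
  scn <- fx$sc_norm
  # duplicate a cell: identical rows must attribute identically
  dup <- expression_matrix(scn$values[c(1, 1, 2), ],
                           gene_ids = scn$gene_ids,
                           row_ids = c("c1", "c1b", "c2"), layer = "lognorm")
  prof <- attribution_profile(dup, fx$fit, steps = 8)
  expect_equal(prof$scores[1, ], prof$scores[2, ], ignore_attr = TRUE)
  # silent genes get exactly zero attribution
  silent <- which(dup$values[3, ] == 0)
  if (length(silent)) {
    expect_true(all(prof$scores[3, silent] == 0))
  }
  expect_true(all(is.finite(prof$scores)))
  expect_equal(length(prof$convergence_gap), 3L)
})

test_that("attribution of a cell ignores the other cells in the matrix", {
  fx <- tiny_trained_fit()
  scn <- fx$sc_norm
  full <- attribution_profile(scn, fx$fit, steps = 8, cells = 5)
  perm <- c(5, setdiff(seq_len(nrow(scn$values)), 5))
  shuffled <- expression_matrix(scn$values[perm, ], gene_ids = scn$gene_ids,
                                row_ids = scn$row_ids[perm], layer = "lognorm")
  moved <- attribution_profile(shuffled, fx$fit, steps = 8, cells = 1)
  expect_equal(unname(full$scores[1, ]), unname(moved$scores[1, ]),
               tolerance = 1e-12)
})

test_that("trajectory pseudotime equals arc length along the fitted curve", {
  # collinear cells, degree 1: pseudotime = distance from the start cell
  xs <- c(0, 1, 2, 3, 4)
  line <- spatial_coords(cbind(xs, 2 * xs + 1))
  traj <- fit_trajectory(line, degree = 1)
  expect_equal(traj$start_cell, line$row_ids[5])  # top-right corner
  d_from_start <- sqrt(rowSums(sweep(line$coords, 2, line$coords[5, ])^2))
  expect_equal(unname(traj$pseudotime), unname(d_from_start), tolerance = 1e-6)
  expect_equal(unname(traj$pseudotime[5]), 0)

  # degree 5 through 6 points interpolates exactly
  set.seed(31)
  six <- spatial_coords(cbind(1:6, rnorm(6)))
  expect_lt(fit_trajectory(six, degree = 5)$residual, 1e-12)

  # parabola arc length from x=0 to x=1: integral of sqrt(1+4x^2)
  par_pts <- seq(0, 1, length.out = 9)
  parab <- spatial_coords(cbind(par_pts, par_pts^2))
  traj2 <- fit_trajectory(parab, degree = 2, start_rule = "min_x")
  oracle <- stats::integrate(function(t) sqrt(1 + 4 * t^2), 0, 1)$value
  expect_equal(oracle, 1.478943, tolerance = 1e-6)
  expect_equal(unname(traj2$pseudotime[9]), oracle, tolerance = 1e-6)

  expect_error(fit_trajectory(spatial_coords(cbind(rep(1, 8), 1:8)), 2),
               "x-coordinates")
  expect_error(fit_trajectory(parab, degree = 20), "at least")
})

test_that("segmenting bins pseudotime into equal-width intervals", {
  xs <- seq(0, 1, length.out = 21)
  line <- spatial_coords(cbind(xs, 0 * xs))
  traj <- fit_trajectory(line, degree = 1, start_rule = "min_x")
  seg2 <- segment_cells(traj, 2)
  expect_equal(unname(seg2[traj$pseudotime < 0.5]),
               rep(1L, sum(traj$pseudotime < 0.5)))
  seg11 <- segment_cells(traj, 11)
  expect_equal(sort(unique(seg11)), 1:11)
  expect_equal(formals(segment_cells)$n_segments, 11L)

  flat <- traj; flat$pseudotime[] <- 1
  expect_warning(s1 <- segment_cells(flat, 4), "one pseudotime")
  expect_true(all(s1 == 1L))
})

test_that("SDG calling finds separated genes and respects the FDR gate", {
  set.seed(32)
  n_per <- 25
  segments <- rep(1:3, each = n_per)
  scores <- matrix(rnorm(3 * n_per * 5, sd = 0.1), ncol = 5,
                   dimnames = list(NULL, paste0("g", 1:5)))
  scores[segments == 2, 3] <- scores[segments == 2, 3] + 1  # separated gene
  hits <- identify_sdgs(scores, segments, fdr = 0.05)
  expect_true(any(hits$gene == "g3" & hits$segment == 2))
  expect_false(any(hits$gene == "g3" & hits$segment != 2))

  # constant scores are never significant
  const <- matrix(1, 3 * n_per, 2, dimnames = list(NULL, c("c1", "c2")))
  expect_equal(nrow(identify_sdgs(const, segments, fdr = 0.05)), 0L)

  # impossible threshold
  expect_equal(nrow(identify_sdgs(scores, segments, fdr = 0)), 0L)

  # undersized segments are excluded with a warning
  segs_bad <- c(segments[-1], 99L)
  expect_warning(identify_sdgs(scores, segs_bad, fdr = 0.05), "fewer than 2")
})

test_that("SDG false positives under label permutation stay near the FDR", {
  set.seed(33)
  n <- 90
  segments <- rep(1:3, each = 30)
  scores <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("g", 1:8)))
  fp <- vapply(1:10, function(s) {
    perm <- sample(segments)
    nrow(identify_sdgs(scores, perm, fdr = 0.05)) / (8 * 3)
  }, numeric(1))
  expect_lte(mean(fp), 0.07)
})
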