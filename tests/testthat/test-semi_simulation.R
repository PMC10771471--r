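test_that("pseudo-spot accumulation matches a hand-built example", {
  # 4 cells around one grid node, 3 anchor cells around the opposite one
  counts <- rbind(c(1, 2), c(0, 1), c(3, 0), c(1, 1),
                  c(2, 2), c(1, 0), c(0, 3))
  sc <- expression_matrix(counts, gene_ids = c("gA", "gB"),
                          row_ids = paste0("c", 1:7))
  coords <- spatial_coords(rbind(c(0.1, 0.1), c(0.2, 0.1), c(0.1, 0.3),
                                 c(0.4, 0.2),
                                 c(10, 10), c(9.8, 10), c(10, 9.7)),
                          row_ids = paste0("c", 1:7))
  labels <- one_hot_annotation(c("a", "a", "a", "b", "a", "a", "a"))
  ds <- generate_pseudo_st(sc, coords, labels, grid = c(2, 2),
                           capture_radius = 1, min_cells = 3)
  expect_equal(nrow(ds$st_expr$values), 2L)
  expect_equal(unname(ds$st_expr$values[1, ]), c(5, 4))
  expect_equal(unname(ds$true_proportions[1, ]), c(0.75, 0.25))
  expect_setequal(ds$membership[[1]], paste0("c", 1:4))
  expect_equal(ds$coverage, 1)
})

test_that("spots below the minimum cell count are removed", {
  counts <- matrix(1, 5, 2)
  sc <- expression_matrix(counts, gene_ids = c("gA", "gB"),
                          row_ids = paste0("c", 1:5))
  # 3 cells near node (0,0); 2 cells near node (10,10)
  coords <- spatial_coords(rbind(c(0, 0), c(0.1, 0), c(0, 0.1),
                                 c(10, 10), c(9.9, 10)),
                          row_ids = paste0("c", 1:5))
  labels <- one_hot_annotation(rep("a", 5))
  ds <- generate_pseudo_st(sc, coords, labels, grid = c(2, 2),
                           capture_radius = 1, min_cells = 3)
  expect_equal(nrow(ds$st_expr$values), 1L)
  expect_equal(length(ds$covered_cell_ids), 3L)
  expect_error(generate_pseudo_st(sc, coords, labels, grid = c(2, 2),
                                  capture_radius = 0.001),
               "capture_radius")
})

test_that("pseudo-ST conserves counts and keeps memberships disjoint", {
  tis <- synthetic_tissue(400, 30, 3, 4, seed = 21)
  r <- calibrate_capture_radius(tis$sc_coords, c(8, 8), 2 / 3)
  ds <- generate_pseudo_st(tis$sc_expr, tis$sc_coords, tis$labels,
                           grid = c(8, 8), capture_radius = r)
  covered <- match(ds$covered_cell_ids, tis$sc_expr$row_ids)
  expect_identical(sum(ds$st_expr$values),
                   sum(tis$sc_expr$values[covered, ]))
  expect_true(all(vapply(ds$membership, length, integer(1)) >= 3))
  all_members <- unlist(ds$membership, use.names = FALSE)
  expect_equal(anyDuplicated(all_members), 0L)
  expect_equal(unname(rowSums(ds$true_proportions)),
               rep(1, nrow(ds$true_proportions)), tolerance = 1e-12)
})

test_that("capture-radius calibration reaches the coverage band or warns", {
  tis <- synthetic_tissue(800, 20, 2, 2, seed = 22)
  r <- calibrate_capture_radius(tis$sc_coords, c(12, 12), 2 / 3)
  ds <- generate_pseudo_st(tis$sc_expr, tis$sc_coords, tis$labels,
                           grid = c(12, 12), capture_radius = r)
  expect_gte(ds$coverage, 0.62)
  expect_lte(ds$coverage, 0.72)

  # near-total coverage with min_cells = 1 once the radius spans a grid cell
  r_full <- calibrate_capture_radius(tis$sc_coords, c(12, 12), 0.999,
                                     min_cells = 1)
  ds_full <- generate_pseudo_st(tis$sc_expr, tis$sc_coords, tis$labels,
                                grid = c(12, 12), capture_radius = r_full,
                                min_cells = 1)
  expect_gte(ds_full$coverage, 0.95)
})

test_that("expression noise is seeded, gene-scaled, and truncation-biased upward", {
  set.seed(23)
  x <- rand_counts(50, 10)
  expect_identical(add_expression_noise(x, 0), x)

  n1 <- add_expression_noise(x, 0.5, seed = 7)
  n2 <- add_expression_noise(x, 0.5, seed = 7)
  expect_identical(n1$values, n2$values)
  expect_true(all(n1$values >= 0))

  # constant genes are untouched at any level
  xc <- expression_matrix(cbind(rep(5, 20), rpois(20, 3)),
                          gene_ids = c("const", "var"))
  nc <- add_expression_noise(xc, 0.8, seed = 1)
  expect_equal(nc$values[, "const"], xc$values[, "const"])

  # zero-heavy gene: truncation at zero inflates the mean monotonically in r
  zg <- expression_matrix(matrix(rbinom(4000, 1, 0.05) * 1, ncol = 2),
                          gene_ids = c("z1", "z2"))
  means <- vapply(c(0.2, 0.5, 0.8), function(r) {
    mean(add_expression_noise(zg, r, seed = 3)$values[, 1])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("synthetic tissues are reproducible with contiguous type domains", {
  t1 <- synthetic_tissue(600, 25, 2, 3, seed = 9)
  t2 <- synthetic_tissue(600, 25, 2, 3, seed = 9)
  expect_identical(t1$sc_expr$values, t2$sc_expr$values)
  expect_identical(t1$sc_coords$coords, t2$sc_coords$coords)
  expect_identical(t1$labels$labels, t2$labels$labels)

  # each type's cells form one connected component at a few neighbor
  # spacings: the type domains are contiguous Voronoi regions
  d <- as.matrix(dist(t1$sc_coords$coords)); diag(d) <- Inf
  radius <- 4 * mean(apply(d, 1, min))
  for (ty in unique(t1$labels$labels)) {
    idx <- which(t1$labels$labels == ty)
    sub <- d[idx, idx] <= radius
    # breadth-first reachability from the first cell
    seen <- rep(FALSE, length(idx)); seen[1] <- TRUE
    frontier <- 1L
    while (length(frontier)) {
      nxt <- which(colSums(sub[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    expect_true(all(seen))
  }
})

test_that("the planted gradient gene tracks the x axis", {
  tis <- synthetic_tissue(500, 40, 3, 5, seed = 10)
  g1 <- tis$archetype_params$spatial_genes[[1]]
  expect_equal(g1$kind, "gradient")
  expect_equal(g1$direction, c(1, 0))
  rho <- cor(tis$sc_expr$values[, g1$gene], tis$sc_coords$coords[, 1],
             method = "spearman")
  expect_gt(rho, 0.5)
})
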