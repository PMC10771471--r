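# Shared fixture builders; everything is generated in code under fixed seeds.

# random row-stochastic matrix
rand_stochastic <- function(n, m = n) {
  w <- matrix(stats::runif(n * m), n, m)
  w / rowSums(w)
}

rand_coords <- function(n, side = 10) {
  spatial_coords(cbind(stats::runif(n, 0, side), stats::runif(n, 0, side)))
}

# small raw-count expression matrix
rand_counts <- function(n, g, mu = 2) {
  expression_matrix(matrix(stats::rnbinom(n * g, mu = mu, size = 2), n, g),
                    gene_ids = sprintf("g%02d", seq_len(g)), layer = "raw")
}

# tiny trained model on a small synthetic tissue; cached per test file
.fixture_cache <- new.env(parent = emptyenv())

tiny_trained_fit <- function() {
  if (!is.null(.fixture_cache$fit)) return(.fixture_cache$fit)
  tis <- synthetic_tissue(n_cells = 250, n_genes = 40, n_types = 3,
                          n_spatial_genes = 6, seed = 11)
  radius <- calibrate_capture_radius(tis$sc_coords, c(8, 8), 2 / 3)
  ds <- generate_pseudo_st(tis$sc_expr, tis$sc_coords, tis$labels,
                           grid = c(8, 8), capture_radius = radius)
  scn <- normalize_expression(tis$sc_expr)
  stn <- normalize_expression(ds$st_expr)
  s <- gaussian_adjacency(ds$st_coords)
  enc <- encoder_config(40, hidden_sizes = 64, latent_dim = 16,
                        st_dropout_rate = sparsity_dropout_rate(tis$sc_expr, ds$st_expr),
                        seed = 5)
  fit <- train_stem(scn, stn, s, enc,
                    train_config(epochs = 60, seed = 5))
  out <- list(tissue = tis, pseudo = ds, sc_norm = scn, st_norm = stn,
              s_truth = s, fit = fit)
  .fixture_cache$fit <- out
  out
}
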