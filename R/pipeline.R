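#' Assemble a full run configuration
#'
#' Collects input locations (or in-memory objects) and stage settings for
#' [run_pipeline()]. Every field is serializable; the resolved
#' configuration is written into the run directory so a run can be
#' reproduced exactly.
#'
#' @param sc_expr,st_expr Raw-count [expression_matrix()] objects or CSV
#'   paths (rows = cells/spots, header = genes, first column = row id).
#' @param st_coords [spatial_coords()] or CSV path (id, x, y).
#' @param sc_labels Optional cell-type label vector, CSV path (id, label)
#'   or [one_hot_annotation()].
#' @param spot_annotation Optional per-spot numeric vector or CSV path
#'   (id, value) to transfer to cells.
#' @param true_coords Optional true cell coordinates (object or CSV) that
#'   switch on the evaluation stage.
#' @param kernel `"gaussian"`, `"exponential"` or `"knn"`.
#' @param kernel_param Bandwidth / scale / k; `NULL` uses
#'   [default_sigma()] for the Gaussian kernel.
#' @param n_hvg Optional number of highly variable genes to restrict to.
#' @param latent_dim,hidden_sizes Encoder geometry.
#' @param alpha,epochs,learning_rate Training settings.
#' @param attribute Run the attribution stage (integrated gradients, SDG
#'   calling along a fitted trajectory).
#' @param steps,n_segments,fdr Attribution settings.
#' @param seed Global seed.
#' @param out_dir Run directory (created if needed).
#' @return A `RunConfig` list.
#' @export
run_config <- function(sc_expr, st_expr, st_coords, sc_labels = NULL,
                       spot_annotation = NULL, true_coords = NULL,
                       kernel = "gaussian", kernel_param = NULL,
                       n_hvg = NULL, latent_dim = 128L, hidden_sizes = 512L,
                       alpha = 0.5, epochs = 400L, learning_rate = 1e-3,
                       attribute = FALSE, steps = 50L, n_segments = 11L,
                       fdr = 0.05, seed = 0L, out_dir = tempfile("spatem_run_")) {
  structure(as.list(environment()), class = "RunConfig")
}

.load_expr <- function(x, layer = "raw") {
  if (inherits(x, "ExpressionMatrix")) return(x)
  if (!file.exists(x)) stop(sprintf("expression file not found: %s", x))
  read_expression_csv(x, layer = layer)
}

.load_coords <- function(x) {
  if (inherits(x, "SpatialCoords")) return(x)
  if (!file.exists(x)) stop(sprintf("coordinates file not found: %s", x))
  read_coords_csv(x)
}

.load_labels <- function(x) {
  if (inherits(x, "CellTypeAnnotation")) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    df <- utils::read.csv(x, row.names = 1)
    return(one_hot_annotation(df[[1]]))
  }
  one_hot_annotation(x)
}

.load_vector <- function(x) {
  if (is.numeric(x)) return(x)
  if (!file.exists(x)) stop(sprintf("annotation file not found: %s", x))
  df <- utils::read.csv(x, row.names = 1)
  stats::setNames(df[[1]], rownames(df))
}

.stage <- function(name, verbose, code) {
  t0 <- Sys.time()
  out <- tryCatch(force(code), error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
  if (verbose) {
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  out
}

#' Run the full mapping pipeline
#'
#' normalize -> align -> spatial adjacency -> train -> mapping products ->
#' (optional) attribution -> (optional) evaluation. All artifacts are
#' written as CSV/JSON into the run directory together with the resolved
#' configuration and a manifest of produced files; reruns with the same
#' configuration are deterministic.
#'
#' @param cfg A [run_config()].
#' @param verbose Log each stage.
#' @return Invisibly, a list with the run directory, manifest, the
#'   `StemFit`, mapping products and (if computed) the evaluation report.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    manifest <<- c(manifest, name)
    path
  }

  sc_raw <- .stage("load", verbose, .load_expr(cfg$sc_expr))
  st_raw <- .load_expr(cfg$st_expr)
  y_st <- .stage("coords", verbose, .load_coords(cfg$st_coords))
  labels <- if (!is.null(cfg$sc_labels)) .load_labels(cfg$sc_labels)

  norm <- .stage("normalize", verbose, {
    list(sc = normalize_expression(sc_raw), st = normalize_expression(st_raw))
  })
  aligned <- .stage("align", verbose, {
    gene_set <- NULL
    if (!is.null(cfg$n_hvg)) {
      hvg_sc <- select_variable_genes(norm$sc, min(cfg$n_hvg, ncol(norm$sc$values)))
      hvg_st <- select_variable_genes(norm$st, min(cfg$n_hvg, ncol(norm$st$values)))
      gene_set <- union(hvg_sc, hvg_st)
    }
    align_genes(norm$sc, norm$st, gene_set = gene_set)
  })

  s_truth <- .stage("adjacency", verbose, {
    switch(cfg$kernel,
      gaussian = gaussian_adjacency(y_st, sigma = if (is.null(cfg$kernel_param))
        default_sigma(y_st) else cfg$kernel_param),
      exponential = exponential_adjacency(y_st, l = cfg$kernel_param),
      knn = knn_adjacency(y_st, k = cfg$kernel_param),
      stop(sprintf("unknown kernel '%s'", cfg$kernel)))
  })

  fit <- .stage("train", verbose, {
    d <- sparsity_dropout_rate(sc_raw, st_raw)
    enc <- encoder_config(n_genes = ncol(aligned$sc$values),
                          hidden_sizes = cfg$hidden_sizes,
                          latent_dim = cfg$latent_dim,
                          st_dropout_rate = d, seed = cfg$seed)
    train_stem(aligned$sc, aligned$st, s_truth, enc,
               train_config(alpha = cfg$alpha, epochs = cfg$epochs,
                            learning_rate = cfg$learning_rate,
                            seed = cfg$seed))
  })
  emit("loss_history.csv", function(p) utils::write.csv(fit$history, p, row.names = FALSE))

  maps <- .stage("map", verbose, cross_mapping(fit$z_sc, fit$z_st))
  y_hat <- pseudo_coordinates(maps$C, y_st)
  adj_sc <- sc_adjacency(fit$z_sc)
  emit("C.csv", function(p) utils::write.csv(maps$C, p))
  emit("Chat.csv", function(p) utils::write.csv(maps$Chat, p))
  emit("pseudo_coords.csv", function(p) write_coords_csv(y_hat, p))
  emit("sc_embeddings.csv", function(p) utils::write.csv(fit$z_sc$vectors, p))
  emit("st_embeddings.csv", function(p) utils::write.csv(fit$z_st$vectors, p))

  if (!is.null(labels)) {
    dec <- deconvolve(maps$Chat, labels)
    emit("proportions.csv", function(p) utils::write.csv(
      as.data.frame(dec$proportions), p))
  }
  if (!is.null(cfg$spot_annotation)) {
    v <- .load_vector(cfg$spot_annotation)
    scores <- transfer_spot_annotation(maps$C, v)
    emit("cell_scores.csv", function(p) utils::write.csv(
      data.frame(cell = rownames(maps$C), score = scores), p, row.names = FALSE))
  }

  sdg <- NULL
  if (isTRUE(cfg$attribute)) {
    sdg <- .stage("attribute", verbose, {
      prof <- attribution_profile(aligned$sc, fit, steps = cfg$steps)
      traj <- fit_trajectory(y_hat, degree = 5)
      segs <- segment_cells(traj, n_segments = cfg$n_segments)
      hits <- identify_sdgs(prof, segs, fdr = cfg$fdr)
      emit("attribution_scores.csv", function(p) utils::write.csv(
        as.data.frame(prof$scores), p))
      emit("sdg_table.csv", function(p) utils::write.csv(hits, p, row.names = FALSE))
      list(profile = prof, trajectory = traj, segments = segs, sdgs = hits)
    })
  }

  report <- NULL
  if (!is.null(cfg$true_coords)) {
    report <- .stage("evaluate", verbose, {
      y_true <- .load_coords(cfg$true_coords)
      rep <- list(mae = coordinate_mae(y_true, y_hat),
                  hit_curve = stats::setNames(
                    vapply(c(10, 20, 50), function(k)
                      hit_number(y_true, adj_sc, min(k, nrow(adj_sc) - 1)),
                      numeric(1)), c("10", "20", "50")))
      emit("report.json", function(p) jsonlite::write_json(
        rep, p, auto_unbox = TRUE, digits = NA))
      rep
    })
  }

  cfg_out <- cfg
  for (f in c("sc_expr", "st_expr", "st_coords", "sc_labels",
              "spot_annotation", "true_coords")) {
    if (!is.null(cfg_out[[f]]) && !is.character(cfg_out[[f]])) {
      cfg_out[[f]] <- sprintf("<in-memory %s>", class(cfg_out[[f]])[1])
    }
  }
  emit("config.yaml", function(p) yaml::write_yaml(
    cfg_out[setdiff(names(cfg_out), "")], p))
  jsonlite::write_json(list(files = manifest, seed = cfg$seed),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  manifest <- c(manifest, "manifest.json")

  invisible(list(out_dir = cfg$out_dir, manifest = manifest, fit = fit,
                 C = maps$C, Chat = maps$Chat, pseudo_coords = y_hat,
                 sc_adjacency = adj_sc, sdg = sdg, report = report))
}
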