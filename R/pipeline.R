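#' Pipeline configuration
#'
#' Collects every stage's tunable parameters with documented defaults. One
#' global `seed` drives all stochastic stages; each stage derives its own
#' seed from it by a fixed offset, so a single knob reproduces a run.
#' Unknown keys are rejected.
#'
#' @param seed global integer seed (default 1).
#' @param io list: `min_counts` (20), `n_top_genes` (2000), `log1p`
#'   (`TRUE`), `normalize` (`TRUE`).
#' @param gmm list: `K` (`"auto"` or an integer), `K_range` (`2:8`, used
#'   when `K = "auto"`), `tol` (`1e-6`), `max_iter` (300), `covariance`
#'   (`"diagonal"` or `"spherical"`).
#' @param cellpop list: `target_pop_size` (20).
#' @param gpr list: `mode` (`"per-cluster"` or `"global"`), `restarts` (3),
#'   `max_train` (1000).
#' @param graph list: `k` (10), `lambda` (3), `beta` (1), `prune_backward`
#'   (`TRUE`).
#' @param trajectory list: `max_paths` (20), `coverage_target` (0.95).
#' @return A `run_config` nested list.
#' @export
run_config <- function(seed = 1L, io = list(), gmm = list(), cellpop = list(),
                       gpr = list(), graph = list(), trajectory = list()) {
  defaults <- list(
    seed = 1L,
    io = list(min_counts = 20, n_top_genes = 2000, log1p = TRUE, normalize = TRUE),
    gmm = list(K = "auto", K_range = 2:8, tol = 1e-6, max_iter = 300L,
               covariance = "diagonal"),
    cellpop = list(target_pop_size = 20),
    gpr = list(mode = "per-cluster", restarts = 3L, max_train = 1000L),
    graph = list(k = 10, lambda = 3, beta = 1, prune_backward = TRUE),
    trajectory = list(max_paths = 20L, coverage_target = 0.95))
  supplied <- list(io = io, gmm = gmm, cellpop = cellpop, gpr = gpr,
                   graph = graph, trajectory = trajectory)
  cfg <- defaults
  cfg$seed <- as.integer(seed)
  for (section in names(supplied)) {
    extra <- setdiff(names(supplied[[section]]), names(defaults[[section]]))
    if (length(extra) > 0)
      stop(sprintf("unknown config key%s in '%s': %s",
                   if (length(extra) > 1) "s" else "", section,
                   paste(extra, collapse = ", ")), call. = FALSE)
    cfg[[section]][names(supplied[[section]])] <- supplied[[section]]
  }
  structure(cfg, class = "run_config")
}

config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("seed", "io", "gmm", "cellpop", "gpr", "graph", "trajectory")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    stop(sprintf("unknown config section(s): %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  do.call(run_config, raw)
}

#' Run the full trajectory-inference pipeline
#'
#' Executes preprocess, mixture clustering (with BIC model selection when
#' `K = "auto"`), cluster refinement into populations, GP velocity
#' smoothing, KNN graph construction, Floyd-Warshall path detection, and
#' per-cell pseudotime assignment. When the dataset carries ground-truth
#' time, rank-agreement metrics are computed per path. Identical seed,
#' config and input give identical outputs.
#'
#' @param ds an [expression_dataset()].
#' @param config a [run_config()].
#' @param output_dir optional directory; when given, all result artifacts
#'   are written there (per-cell CSV, edge-list CSV, GraphML, path JSON,
#'   metrics JSON, resolved config YAML).
#' @param verbose emit per-stage progress messages.
#' @return A `poptraj_result`: list with `dataset` (preprocessed), `model`,
#'   `K_selection` (BIC table or `NULL`), `populations`, `graph`,
#'   `shortest_paths`, `trajectories`, `cell_times`, `per_cell` (tibble:
#'   `cell_id`, `population_id`, `path_id`, `pseudotime`), `metrics`
#'   (`NULL` without ground truth), `config`.
#' @export
run_pipeline <- function(ds, config = run_config(), output_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!inherits(config, "run_config")) stop("config must be a run_config()", call. = FALSE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    pt_log(verbose, "stage %-12s %6.2fs", name,
           as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  pp <- stage("preprocess", preprocess(
    ds, min_counts = config$io$min_counts, n_top_genes = config$io$n_top_genes,
    log1p = config$io$log1p, normalize = config$io$normalize))

  gmm_stage <- stage("gmm", {
    if (identical(config$gmm$K, "auto")) {
      sel <- select_K(pp, K_range = config$gmm$K_range,
                      seed = derive_seed(config$seed, 1),
                      tol = config$gmm$tol, max_iter = config$gmm$max_iter,
                      covariance = config$gmm$covariance)
      list(model = sel$models[[paste0("K", sel$K)]], bic = sel$bic)
    } else {
      list(model = fit_gmm(pp, K = config$gmm$K,
                           seed = derive_seed(config$seed, 1),
                           tol = config$gmm$tol, max_iter = config$gmm$max_iter,
                           covariance = config$gmm$covariance),
           bic = NULL)
    }
  })
  model <- gmm_stage$model
  K_selection <- gmm_stage$bic
  pt_log(verbose, "  K = %d clusters", model$K)

  pops <- stage("cellpop", refine_clusters(
    pp, model, target_pop_size = config$cellpop$target_pop_size,
    seed = derive_seed(config$seed, 2)))
  pops <- stage("gpr", smooth_population_velocities(
    pp, pops, mode = config$gpr$mode, restarts = config$gpr$restarts,
    seed = derive_seed(config$seed, 3), max_train = config$gpr$max_train,
    verbose = verbose))
  g <- stage("graph", build_knn_graph(
    pops, k = config$graph$k, lambda = config$graph$lambda,
    beta = config$graph$beta, prune_backward = config$graph$prune_backward))
  fw <- stage("floyd-warshall", floyd_warshall(g))
  trajs <- stage("trajectories", detect_trajectories(
    g, fw, max_paths = config$trajectory$max_paths,
    coverage_target = config$trajectory$coverage_target))
  times <- stage("pseudotime", assign_pseudotime(trajs, pops, pp))
  per_cell <- cell_time_table(times, pops, pp$cell_ids)

  metrics <- NULL
  if (!is.null(pp$truth_time)) {
    metrics <- stage("metrics", evaluate_pseudotime(times, pp$truth_time))
  }

  res <- structure(
    list(dataset = pp, model = model, K_selection = K_selection,
         populations = pops, graph = g, shortest_paths = fw,
         trajectories = trajs, cell_times = times, per_cell = per_cell,
         metrics = metrics, config = config),
    class = "poptraj_result")
  if (!is.null(output_dir)) write_results(res, output_dir)
  res
}

#' @export
print.poptraj_result <- function(x, ...) {
  cat(sprintf("<poptraj_result> %d cells, %d genes after preprocessing\n",
              length(x$dataset$cell_ids), length(x$dataset$gene_ids)))
  cat(sprintf("  %d clusters -> %d populations -> %d trajectories\n",
              x$model$K, nrow(x$populations), nrow(x$trajectories)))
  if (!is.null(x$metrics)) {
    cat(sprintf("  mean Kendall %.4f, mean Spearman %.4f over %d path(s)\n",
                x$metrics$summary$kendall, x$metrics$summary$spearman,
                nrow(x$metrics$per_path)))
  }
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' @param res a `poptraj_result`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(res$per_cell), file.path(dir, "cells.csv"),
            row.names = FALSE)
  write_graph(res$graph, file.path(dir, "graph_edges.csv"), "edgelist")
  write_graph(res$graph, file.path(dir, "graph.graphml"), "graphml")
  paths <- lapply(seq_len(nrow(res$trajectories)), function(i) {
    list(path_id = res$trajectories$path_id[i],
         pop_sequence = res$trajectories$pop_sequence[[i]],
         n_pops = res$trajectories$n_pops[i],
         total_weight = res$trajectories$total_weight[i])
  })
  jsonlite::write_json(paths, file.path(dir, "paths.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(res$metrics)) {
    jsonlite::write_json(
      list(per_path = res$metrics$per_path, summary = res$metrics$summary),
      file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }
  cfg <- unclass(res$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
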