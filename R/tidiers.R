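#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted mixture model
#'
#' @param x a `mixture_model` from [fit_gmm()].
#' @param ... unused.
#' @return A tibble with one row per component: `component`, `weight`,
#'   `size` (hard-assignment count), `mean_norm` (Euclidean norm of the
#'   component mean), `mean_variance`.
#' @export
tidy.mixture_model <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$K),
    weight = x$weights,
    size = as.integer(tabulate(x$assignments, nbins = x$K)),
    mean_norm = sqrt(rowSums(x$means^2)),
    mean_variance = rowMeans(x$variances))
}

#' One-row summary of a fitted mixture model
#'
#' @inheritParams tidy.mixture_model
#' @return A tibble with `K`, `log_likelihood`, `n_iter`, `converged`,
#'   `n_cells`, `n_genes`.
#' @export
glance.mixture_model <- function(x, ...) {
  tibble::tibble(
    K = x$K,
    log_likelihood = utils::tail(x$log_likelihood_trace, 1),
    n_iter = x$n_iter,
    converged = x$converged,
    n_cells = x$n_cells,
    n_genes = x$n_genes)
}

#' One-row summary of a GP regression model
#'
#' @param x a `gpr_model` from [fit_gpr()].
#' @param ... unused.
#' @return A tibble with the hyperparameters and the negative log marginal
#'   likelihood.
#' @export
glance.gpr_model <- function(x, ...) {
  tibble::tibble(
    sigma = x$sigma, l = x$l, sigma_rbf = x$sigma_rbf,
    n_train = nrow(x$inputs), n_outputs = ncol(x$targets), nll = x$nll)
}

#' Per-cell tidy output of a pipeline run
#'
#' @param x a `poptraj_result` from [run_pipeline()].
#' @param ... unused.
#' @return The per-cell tibble (`cell_id`, `population_id`, `path_id`,
#'   `pseudotime`), joined with ground truth when present.
#' @export
tidy.poptraj_result <- function(x, ...) {
  out <- x$per_cell
  truth <- dataset_truth(x$dataset)
  if (!is.null(truth)) out <- dplyr::left_join(out, truth, by = "cell_id")
  out
}

#' One-row summary of a pipeline run
#'
#' @inheritParams tidy.poptraj_result
#' @return A tibble with cluster/population/path counts and, when ground
#'   truth is available, the mean Kendall and Spearman agreement.
#' @export
glance.poptraj_result <- function(x, ...) {
  out <- tibble::tibble(
    n_cells = length(x$dataset$cell_ids),
    n_genes = length(x$dataset$gene_ids),
    K = x$model$K,
    n_populations = nrow(x$populations),
    n_edges = nrow(x$graph$edges),
    n_paths = nrow(x$trajectories),
    assigned_frac = mean(!is.na(x$per_cell$pseudotime)))
  if (!is.null(x$metrics)) {
    out$kendall <- x$metrics$summary$kendall
    out$spearman <- x$metrics$summary$spearman
  }
  out
}
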