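#' Rank-based agreement between inferred and true orderings
#'
#' Two statistics quantify how well inferred pseudotime reproduces a known
#' ordering: a tie-corrected Kendall coefficient with an absolute-value
#' numerator (range \[0,1\]; 1 means a perfectly monotone relation in either
#' direction), and the Spearman rank correlation (range \[-1,1\]).
#'
#' @name metrics
NULL

# concordant/discordant/tie pair counts, vectorized over all pairs
tau_pair_counts <- function(pred, true) {
  sp <- sign(outer(pred, pred, "-"))
  st <- sign(outer(true, true, "-"))
  up <- upper.tri(sp)
  prod_ <- sp[up] * st[up]
  C <- sum(prod_ > 0)
  D <- sum(prod_ < 0)
  tie_pred <- sum(sp[up] == 0 & st[up] != 0)
  tie_true <- sum(st[up] == 0 & sp[up] != 0)
  tie_both <- sum(sp[up] == 0 & st[up] == 0)
  list(C = C, D = D, tie_pred = tie_pred, tie_true = tie_true, tie_both = tie_both)
}

#' Absolute-numerator Kendall tau-b
#'
#' \eqn{\tau_b = |C - D| / \sqrt{(C + D + T_1)(C + D + T_2)}} where C and D
#' count concordant and discordant pairs and \eqn{T_1, T_2} count pairs tied
#' only in the predicted or only in the true ordering. The absolute value in
#' the numerator folds the usual \[-1,1\] range onto \[0,1\]: pseudotime
#' running exactly backwards along a path is still a perfect ordering.
#'
#' @param pred,true numeric vectors of equal length \eqn{\ge 2} (times or
#'   ranks).
#' @return The statistic, in \[0,1\].
#' @export
kendall_tau_b_abs <- function(pred, true) {
  if (length(pred) != length(true)) stop("pred and true differ in length", call. = FALSE)
  if (length(pred) < 2) stop("need at least 2 observations", call. = FALSE)
  cnt <- tau_pair_counts(pred, true)
  den1 <- cnt$C + cnt$D + cnt$tie_pred
  den2 <- cnt$C + cnt$D + cnt$tie_true
  if (den1 == 0 || den2 == 0)
    stop("tau-b undefined: one of the orderings is entirely tied", call. = FALSE)
  abs(cnt$C - cnt$D) / sqrt(den1 * den2)
}

#' Spearman rank correlation
#'
#' Values are converted to ranks (ties get average rank) and the Pearson
#' product-moment correlation of the two rank vectors is computed.
#'
#' @inheritParams kendall_tau_b_abs
#' @return The coefficient, in \[-1,1\].
#' @export
spearman_rho <- function(pred, true) {
  if (length(pred) != length(true)) stop("pred and true differ in length", call. = FALSE)
  if (length(pred) < 2) stop("need at least 2 observations", call. = FALSE)
  rp <- rank(pred, ties.method = "average")
  rt <- rank(true, ties.method = "average")
  dp <- rp - mean(rp); dt <- rt - mean(rt)
  sp <- sqrt(sum(dp^2)); st <- sqrt(sum(dt^2))
  if (sp == 0 || st == 0)
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  sum(dt * dp) / (st * sp)
}

#' Evaluate inferred pseudotime against ground truth, per path
#'
#' For each detected path, both statistics are computed between the path's
#' pseudotime and the ground-truth time restricted to that path's cells;
#' the unweighted mean across paths summarises the run.
#'
#' @param times a `cell_times` tibble from [assign_pseudotime()].
#' @param truth_time numeric vector of ground-truth times indexed by cell
#'   row, or a tibble with columns `cell_id`/`truth_time` plus `cell_ids`.
#' @param cell_ids optional character vector mapping cell row indices to
#'   ids (required when `truth_time` is a tibble).
#' @return A list with `per_path` (tibble: `path_id`, `n_cells`, `kendall`,
#'   `spearman`) and `summary` (tibble: mean `kendall` and `spearman`).
#' @export
evaluate_pseudotime <- function(times, truth_time, cell_ids = NULL) {
  if (is.data.frame(truth_time)) {
    if (is.null(cell_ids)) stop("cell_ids required with a truth tibble", call. = FALSE)
    truth_time <- truth_time$truth_time[match(cell_ids, truth_time$cell_id)]
  }
  per_path <- times |>
    dplyr::group_by(.data$path_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      kendall = kendall_tau_b_abs(.data$pseudotime, truth_time[.data$cell]),
      spearman = spearman_rho(.data$pseudotime, truth_time[.data$cell]),
      .groups = "drop")
  list(per_path = per_path,
       summary = tibble::tibble(kendall = mean(per_path$kendall),
                                spearman = mean(per_path$spearman)))
}
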