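#' Basic preprocessing of an expression dataset
#'
#' Standard single-cell preprocessing applied ahead of clustering, mirroring
#' the usual velocity-workflow protocol: drop weakly expressed genes,
#' library-size normalize each cell to the median total, optionally
#' log-transform, and optionally restrict to the most highly dispersed genes.
#' All gene subsetting is applied identically to the spliced, unspliced and
#' velocity layers; cells are never reordered or dropped. The velocity layer
#' is never normalized or log-transformed: it is taken to be already on the
#' working expression scale, as produced upstream.
#'
#' @param ds an [expression_dataset()].
#' @param min_counts genes whose total spliced signal across cells falls
#'   below this threshold are removed (default 20).
#' @param n_top_genes keep at most this many genes, ranked by dispersion
#'   (variance/mean of spliced expression); default 2000. Values at or above
#'   the current gene count keep everything.
#' @param log1p apply `log(1 + x)` to the spliced and unspliced layers
#'   (default `TRUE`).
#' @param normalize per-cell library-size normalization of spliced and
#'   unspliced to the median pre-normalization total (default `TRUE`).
#' @return A preprocessed [expression_dataset()].
#' @export
preprocess <- function(ds, min_counts = 20, n_top_genes = 2000,
                       log1p = TRUE, normalize = TRUE) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (min_counts < 0) stop("min_counts must be >= 0", call. = FALSE)
  if (n_top_genes < 1) stop("n_top_genes must be >= 1", call. = FALSE)

  keep <- colSums(ds$spliced) >= min_counts
  if (!any(keep)) {
    stop(sprintf("all %d genes fall below min_counts = %g; nothing left to analyse",
                 n_genes(ds), min_counts), call. = FALSE)
  }
  spliced <- ds$spliced[, keep, drop = FALSE]
  unspliced <- ds$unspliced[, keep, drop = FALSE]
  velocity <- ds$velocity[, keep, drop = FALSE]

  if (normalize) {
    totals <- rowSums(spliced)
    target <- median(totals)
    scale_s <- ifelse(totals > 0, target / totals, 1)
    spliced <- spliced * scale_s
    totals_u <- rowSums(unspliced)
    target_u <- median(totals_u)
    scale_u <- ifelse(totals_u > 0, target_u / totals_u, 1)
    unspliced <- unspliced * scale_u
  }
  if (log1p) {
    spliced <- log1p(spliced)
    unspliced <- log1p(unspliced)
  }
  if (n_top_genes < ncol(spliced)) {
    mu <- colMeans(spliced)
    v <- apply(spliced, 2L, var)
    dispersion <- ifelse(mu > 0, v / mu, 0)
    top <- order(dispersion, decreasing = TRUE)[seq_len(n_top_genes)]
    top <- sort(top)  # preserve the original gene order
    spliced <- spliced[, top, drop = FALSE]
    unspliced <- unspliced[, top, drop = FALSE]
    velocity <- velocity[, top, drop = FALSE]
  }
  expression_dataset(spliced, unspliced, velocity,
                     cell_ids = ds$cell_ids, gene_ids = colnames(spliced),
                     truth_time = ds$truth_time, truth_branch = ds$truth_branch)
}
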