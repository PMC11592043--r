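#' Expression dataset with spliced, unspliced and velocity layers
#'
#' Container for the three aligned cells-by-genes matrices the trajectory
#' pipeline consumes: spliced counts (or normalized expression), unspliced
#' counts, and RNA velocity in expression units per unit time. Velocity is an
#' input computed upstream (e.g. by a velocity estimation tool); it is never
#' estimated here. Optional ground truth (per-cell time in \[0,1\] and branch
#' label) supports evaluation on simulated data.
#'
#' @param spliced,unspliced,velocity numeric matrices of identical dimension,
#'   cells in rows, genes in columns. Sparse `Matrix` input is densified.
#' @param cell_ids,gene_ids character vectors of unique identifiers; default
#'   to the dimnames of `spliced`, or `cell_1..m` / `gene_1..n`.
#' @param truth_time optional numeric vector of length m with values in
#'   \[0,1\]: ground-truth developmental time.
#' @param truth_branch optional vector of length m with branch labels.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `spliced`, `unspliced`, `velocity` (dense matrices with dimnames),
#'   `cell_ids`, `gene_ids`, `truth_time`, `truth_branch`.
#' @export
expression_dataset <- function(spliced, unspliced, velocity,
                               cell_ids = NULL, gene_ids = NULL,
                               truth_time = NULL, truth_branch = NULL) {
  dense <- function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  }
  spliced <- dense(spliced)
  layers <- list(spliced = spliced,
                 unspliced = dense(unspliced),
                 velocity = dense(velocity))
  m <- nrow(spliced); n <- ncol(spliced)
  for (nm in names(layers)) {
    if (!identical(dim(layers[[nm]]), c(m, n))) {
      stop(sprintf(
        "layer '%s' has dimension %d x %d but 'spliced' is %d x %d",
        nm, nrow(layers[[nm]]), ncol(layers[[nm]]), m, n), call. = FALSE)
    }
    if (anyNA(layers[[nm]]) || any(!is.finite(layers[[nm]])))
      stop(sprintf("layer '%s' contains non-finite values", nm), call. = FALSE)
  }
  cell_ids <- as.character(cell_ids %||% rownames(spliced) %||% paste0("cell_", seq_len(m)))
  gene_ids <- as.character(gene_ids %||% colnames(spliced) %||% paste0("gene_", seq_len(n)))
  if (length(cell_ids) != m) stop("cell_ids must have one entry per row", call. = FALSE)
  if (length(gene_ids) != n) stop("gene_ids must have one entry per column", call. = FALSE)
  if (anyDuplicated(cell_ids)) stop("cell_ids contain duplicates", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("gene_ids contain duplicates", call. = FALSE)
  if (!is.null(truth_time)) {
    truth_time <- as.numeric(truth_time)
    if (length(truth_time) != m) stop("truth_time must have length m", call. = FALSE)
    if (any(truth_time < 0 | truth_time > 1))
      stop("truth_time values must lie in [0,1]", call. = FALSE)
  }
  if (!is.null(truth_branch)) {
    truth_branch <- as.character(truth_branch)
    if (length(truth_branch) != m) stop("truth_branch must have length m", call. = FALSE)
  }
  layers <- lapply(layers, function(x) {
    dimnames(x) <- list(cell_ids, gene_ids)
    x
  })
  structure(
    list(spliced = layers$spliced, unspliced = layers$unspliced,
         velocity = layers$velocity,
         cell_ids = cell_ids, gene_ids = gene_ids,
         truth_time = truth_time, truth_branch = truth_branch),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d cells x %d genes\n",
              length(x$cell_ids), length(x$gene_ids)))
  cat("  layers: spliced, unspliced, velocity\n")
  if (!is.null(x$truth_time)) cat("  ground truth: time")
  if (!is.null(x$truth_branch)) cat(", branch")
  if (!is.null(x$truth_time) || !is.null(x$truth_branch)) cat("\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$spliced)

n_cells <- function(ds) nrow(ds$spliced)
n_genes <- function(ds) ncol(ds$spliced)

#' Ground truth as a tibble
#'
#' @param ds an [expression_dataset()].
#' @return A tibble with columns `cell_id`, `truth_time`, `truth_branch`
#'   (absent columns dropped), or `NULL` when the dataset carries no truth.
#' @export
dataset_truth <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(ds$truth_time) && is.null(ds$truth_branch)) return(NULL)
  out <- tibble::tibble(cell_id = ds$cell_ids)
  if (!is.null(ds$truth_time)) out$truth_time <- ds$truth_time
  if (!is.null(ds$truth_branch)) out$truth_branch <- ds$truth_branch
  out
}
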