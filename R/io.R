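#' Read an expression dataset from disk
#'
#' Two on-disk dialects are supported. `"mtx-triplet"`: a directory with
#' `spliced.mtx`, `unspliced.mtx`, `velocity.mtx` (Matrix Market, cells in
#' rows) plus `cells.tsv` and `genes.tsv` (two columns: index, id; no
#' header). `"delimited"`: a directory with `spliced.csv`, `unspliced.csv`,
#' `velocity.csv`, dense matrices with cell ids as row names and gene ids as
#' header. Either dialect may carry an optional `truth.csv` with columns
#' `cell_id`, `truth_time` and optionally `truth_branch`. The layer names are
#' fixed: a dataset without a velocity layer is rejected, because velocity
#' must be computed upstream before trajectory inference.
#'
#' @param path directory containing the files above.
#' @param format one of `"mtx-triplet"`, `"delimited"`, `"h5container"`.
#' @return An [expression_dataset()].
#' @export
load_dataset <- function(path, format = c("mtx-triplet", "delimited", "h5container")) {
  format <- match.arg(format)
  if (format == "h5container") {
    stop("HDF5 single-cell containers are not readable in this build; ",
         "export the 'spliced', 'unspliced' and 'velocity' layers to the ",
         "mtx-triplet or delimited dialect instead", call. = FALSE)
  }
  if (!dir.exists(path)) stop(sprintf("no such directory: %s", path), call. = FALSE)
  if (format == "mtx-triplet") {
    read_layer <- function(nm) {
      f <- file.path(path, paste0(nm, ".mtx"))
      if (!file.exists(f)) {
        if (nm == "velocity")
          stop("missing velocity layer: RNA velocity must be computed upstream ",
               "(e.g. with a velocity estimation tool) and supplied as velocity.mtx",
               call. = FALSE)
        stop(sprintf("missing layer file: %s", f), call. = FALSE)
      }
      as.matrix(Matrix::readMM(f))
    }
    layers <- lapply(c(spliced = "spliced", unspliced = "unspliced",
                       velocity = "velocity"), read_layer)
    cells <- read.delim(file.path(path, "cells.tsv"), header = FALSE,
                        stringsAsFactors = FALSE)
    genes <- read.delim(file.path(path, "genes.tsv"), header = FALSE,
                        stringsAsFactors = FALSE)
    cell_ids <- as.character(cells[[ncol(cells)]])
    gene_ids <- as.character(genes[[ncol(genes)]])
  } else {
    read_layer <- function(nm) {
      f <- file.path(path, paste0(nm, ".csv"))
      if (!file.exists(f)) {
        if (nm == "velocity")
          stop("missing velocity layer: RNA velocity must be computed upstream ",
               "and supplied as velocity.csv", call. = FALSE)
        stop(sprintf("missing layer file: %s", f), call. = FALSE)
      }
      as.matrix(read.csv(f, row.names = 1, check.names = FALSE))
    }
    layers <- lapply(c(spliced = "spliced", unspliced = "unspliced",
                       velocity = "velocity"), read_layer)
    cell_ids <- rownames(layers$spliced)
    gene_ids <- colnames(layers$spliced)
  }
  for (nm in c("unspliced", "velocity")) {
    if (!identical(dim(layers[[nm]]), dim(layers$spliced)))
      stop(sprintf(
        "dimension mismatch in layer '%s': %d x %d, expected %d x %d from 'spliced'",
        nm, nrow(layers[[nm]]), ncol(layers[[nm]]),
        nrow(layers$spliced), ncol(layers$spliced)), call. = FALSE)
  }
  truth_time <- NULL; truth_branch <- NULL
  tf <- file.path(path, "truth.csv")
  if (file.exists(tf)) {
    tr <- read.csv(tf, stringsAsFactors = FALSE)
    ord <- match(cell_ids, tr$cell_id)
    if (anyNA(ord)) stop("truth.csv does not cover all cells", call. = FALSE)
    if ("truth_time" %in% names(tr)) truth_time <- tr$truth_time[ord]
    if ("truth_branch" %in% names(tr)) truth_branch <- tr$truth_branch[ord]
  }
  expression_dataset(layers$spliced, layers$unspliced, layers$velocity,
                     cell_ids = cell_ids, gene_ids = gene_ids,
                     truth_time = truth_time, truth_branch = truth_branch)
}

#' Write an expression dataset to disk
#'
#' Inverse of [load_dataset()]; the round trip reproduces all three layers
#' and the identifiers exactly.
#'
#' @param ds an [expression_dataset()].
#' @param path output directory (created if absent).
#' @param format `"mtx-triplet"` or `"delimited"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, format = c("mtx-triplet", "delimited")) {
  stopifnot(inherits(ds, "expression_dataset"))
  format <- match.arg(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (format == "mtx-triplet") {
    for (nm in c("spliced", "unspliced", "velocity")) {
      Matrix::writeMM(Matrix::Matrix(ds[[nm]], sparse = TRUE),
                      file.path(path, paste0(nm, ".mtx")))
    }
    write.table(data.frame(seq_along(ds$cell_ids), ds$cell_ids),
                file.path(path, "cells.tsv"), sep = "\t",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
    write.table(data.frame(seq_along(ds$gene_ids), ds$gene_ids),
                file.path(path, "genes.tsv"), sep = "\t",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    for (nm in c("spliced", "unspliced", "velocity")) {
      write.csv(as.data.frame(ds[[nm]]), file.path(path, paste0(nm, ".csv")))
    }
  }
  truth <- dataset_truth(ds)
  if (!is.null(truth)) {
    write.csv(truth, file.path(path, "truth.csv"), row.names = FALSE)
  }
  invisible(path)
}
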