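#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# 2-D PCA coordinates of cells and population centroids, shared fit
result_embedding <- function(res) {
  x <- res$dataset$spliced
  pca <- stats::prcomp(x, rank. = 2, center = TRUE, scale. = FALSE)
  cells <- tibble::as_tibble(pca$x, .name_repair = "minimal")
  names(cells) <- c("PC1", "PC2")
  cells$cell_id <- res$dataset$cell_ids
  cent <- stats::predict(pca, centroid_matrix(res$populations))
  pops <- tibble::tibble(pop_id = res$populations$pop_id,
                         PC1 = cent[, 1], PC2 = cent[, 2])
  list(cells = cells, pops = pops)
}

#' Plot a pipeline result
#'
#' `type = "pseudotime"` shows cells in PCA space colored by inferred
#' pseudotime; `type = "graph"` overlays population centroids and the
#' directed KNN edges; `type = "trajectories"` draws each detected path
#' through its population centroids.
#'
#' @param object a `poptraj_result` from [run_pipeline()].
#' @param type one of `"pseudotime"`, `"graph"`, `"trajectories"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.poptraj_result <- function(object, type = c("pseudotime", "graph",
                                                     "trajectories"), ...) {
  type <- match.arg(type)
  emb <- result_embedding(object)
  cells <- dplyr::left_join(emb$cells, object$per_cell, by = "cell_id")
  base <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$PC1, y = .data$PC2))

  if (type == "pseudotime") {
    return(base +
             ggplot2::geom_point(ggplot2::aes(colour = .data$pseudotime),
                                 size = 0.8) +
             ggplot2::scale_colour_viridis_c(na.value = "grey80") +
             ggplot2::labs(colour = "pseudotime") +
             ggplot2::theme_minimal())
  }
  if (type == "graph") {
    seg <- object$graph$edges |>
      dplyr::left_join(emb$pops, by = c(from = "pop_id")) |>
      dplyr::left_join(emb$pops, by = c(to = "pop_id"),
                       suffix = c("", "_to"))
    return(base +
             ggplot2::geom_point(colour = "grey85", size = 0.6) +
             ggplot2::geom_segment(
               data = seg,
               ggplot2::aes(x = .data$PC1, y = .data$PC2,
                            xend = .data$PC1_to, yend = .data$PC2_to,
                            linewidth = 1 / .data$weight),
               arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
               colour = "steelblue", alpha = 0.6) +
             ggplot2::scale_linewidth(range = c(0.1, 0.8), guide = "none") +
             ggplot2::geom_point(data = emb$pops, colour = "black", size = 1.5) +
             ggplot2::theme_minimal())
  }
  paths <- object$trajectories |>
    dplyr::mutate(step = purrr::map(.data$pop_sequence, ~ tibble::tibble(pop_id = .x))) |>
    dplyr::select("path_id", "step") |>
    tidyr::unnest("step") |>
    dplyr::left_join(emb$pops, by = "pop_id")
  base +
    ggplot2::geom_point(colour = "grey85", size = 0.6) +
    ggplot2::geom_path(data = paths,
                       ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                    colour = factor(.data$path_id)),
                       arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                       linewidth = 0.7) +
    ggplot2::labs(colour = "path") +
    ggplot2::theme_minimal()
}

#' Plot the BIC curve of mixture model selection
#'
#' @param bic_table the `bic` tibble returned by [select_K()] (or the
#'   `K_selection` element of a pipeline result).
#' @return A ggplot object.
#' @export
plot_K_selection <- function(bic_table) {
  ggplot2::ggplot(bic_table, ggplot2::aes(x = .data$K, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(y = "BIC") +
    ggplot2::theme_minimal()
}
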