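#' Directed weighted KNN graph over cell populations
#'
#' Each population is linked to its k nearest populations by centroid
#' distance. An edge from CP_s to CP_q carries two dissimilarities: the
#' expression difference \eqn{l_\alpha = 1 - \cos\alpha}, where
#' \eqn{\cos\alpha} is the cosine between the displacement
#' \eqn{X^*_q - X^*_s} and the source velocity \eqn{v_s} (an edge pointing
#' where the velocity points scores 0, an edge pointing against it scores
#' 2), and the distance difference \eqn{l_d = d_{s,q} / d_{\max}} with
#' \eqn{d_{\max}} the largest retained candidate distance over the whole
#' graph. The edge weight combines them nonlinearly:
#' \eqn{e_{s,q} = \lambda^{\,l_\alpha + \beta l_d} / \lambda}, strictly
#' increasing in both terms for \eqn{\lambda > 1}.
#'
#' @name graph
NULL

#' Velocity-alignment dissimilarity between two populations
#'
#' @param centroid_s,centroid_q centroids of the source and target CPs.
#' @param v_s velocity of the source CP.
#' @return \eqn{l_\alpha = 1 - \cos\alpha \in [0, 2]}.
#' @export
expression_difference <- function(centroid_s, centroid_q, v_s) {
  disp <- centroid_q - centroid_s
  nd <- sqrt(sum(disp^2)); nv <- sqrt(sum(v_s^2))
  if (nv == 0) stop("source population has zero velocity", call. = FALSE)
  if (nd == 0) stop("coincident population centroids", call. = FALSE)
  1 - sum(disp * v_s) / (nd * nv)
}

#' Nonlinear edge weight from alignment and distance dissimilarities
#'
#' @param l_alpha velocity-alignment dissimilarity in \[0, 2\].
#' @param l_d normalized distance in \[0, 1\].
#' @param lambda weight base, `> 1`.
#' @param beta distance factor, `> 0`.
#' @return \eqn{e = \lambda^{\,l_\alpha + \beta l_d} / \lambda}.
#' @export
edge_weight <- function(l_alpha, l_d, lambda, beta) {
  lambda^(l_alpha + beta * l_d) / lambda
}

#' Build the directed weighted KNN population graph
#'
#' @param pops a `cell_populations` tibble with velocities filled
#'   (see [smooth_population_velocities()]).
#' @param k out-degree: number of nearest neighbours per population
#'   (clamped to one less than the population count, with a warning).
#' @param lambda weight base, `> 1`; scales the nonlinear combination.
#' @param beta distance factor, `> 0`; balances `l_d` against `l_alpha`.
#' @param prune_backward drop edges at more than 90 degrees to the source
#'   velocity (`l_alpha > 1`) after weighting (default `TRUE`).
#' @return A `population_graph`: list with `nodes` (the `pops` tibble),
#'   `edges` (tibble: `from`, `to`, `dist`, `l_alpha`, `l_d`, `weight`),
#'   `k`, `lambda`, `beta`, `d_max`.
#' @export
build_knn_graph <- function(pops, k = 10, lambda = 3, beta = 1,
                            prune_backward = TRUE) {
  G <- nrow(pops)
  if (G < 2) stop("need at least 2 populations to build a graph", call. = FALSE)
  if (lambda <= 1) stop("lambda must be > 1", call. = FALSE)
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k >= G) {
    warning(sprintf("k = %d >= %d populations; clamped to %d", k, G, G - 1))
    k <- G - 1
  }
  cent <- centroid_matrix(pops)
  vel <- velocity_matrix(pops)
  d2 <- pairwise_sqdist(cent, cent)
  d <- sqrt(d2)

  from <- integer(0); to <- integer(0); dd <- numeric(0)
  for (s in seq_len(G)) {
    cand <- setdiff(order(d[s, ]), s)[seq_len(k)]
    from <- c(from, rep(s, k)); to <- c(to, cand); dd <- c(dd, d[s, cand])
  }
  d_max <- max(dd)
  if (d_max <= 0) stop("all population centroids coincide", call. = FALSE)

  l_alpha <- vapply(seq_along(from), function(i) {
    expression_difference(cent[from[i], ], cent[to[i], ], vel[from[i], ])
  }, numeric(1))
  l_d <- dd / d_max
  weight <- edge_weight(l_alpha, l_d, lambda, beta)

  edges <- tibble::tibble(
    from = pops$pop_id[from], to = pops$pop_id[to],
    dist = dd, l_alpha = l_alpha, l_d = l_d, weight = weight)
  if (prune_backward) {
    edges <- edges[edges$l_alpha <= 1, , drop = FALSE]
  }
  structure(
    list(nodes = pops, edges = edges, k = k, lambda = lambda, beta = beta,
         d_max = d_max),
    class = "population_graph")
}

#' @export
print.population_graph <- function(x, ...) {
  cat(sprintf("<population_graph> %d populations, %d directed edges (k = %d, lambda = %g, beta = %g)\n",
              nrow(x$nodes), nrow(x$edges), x$k, x$lambda, x$beta))
  invisible(x)
}

#' Convert a population graph to igraph
#'
#' @param g a `population_graph`.
#' @return An `igraph` directed graph with edge attributes `weight`,
#'   `l_alpha`, `l_d`, `dist`.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "population_graph"))
  igraph::graph_from_data_frame(
    as.data.frame(g$edges),
    directed = TRUE,
    vertices = data.frame(name = g$nodes$pop_id,
                          parent_cluster = g$nodes$parent_cluster,
                          n_cells = g$nodes$n_cells))
}

#' Write a population graph to disk
#'
#' @param g a `population_graph`.
#' @param path output file; `format = "edgelist"` writes the edge tibble as
#'   CSV, `"graphml"` writes GraphML via igraph.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    write.csv(as.data.frame(g$edges), path, row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph(g), path, format = "graphml")
  }
  invisible(path)
}

#' Read an edge-list CSV back into a graph skeleton
#'
#' Round-trips the edge table written by [write_graph()]; node metadata is
#' not reconstructed.
#'
#' @param path edge-list CSV path.
#' @return A tibble with the edge columns.
#' @export
read_graph_edges <- function(path) {
  tibble::as_tibble(read.csv(path))
}
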