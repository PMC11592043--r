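#' Trajectory detection and per-cell pseudotime
#'
#' All-pairs shortest paths over the population graph (Floyd-Warshall, which
#' tolerates negative edge weights) provide candidate trajectories between
#' source populations (in-degree 0) and sink populations (out-degree 0).
#' Paths are selected greedily by coverage of not-yet-covered populations.
#' Within each population, cells are ordered by orthogonal projection onto
#' the population's velocity line, and times are min-max normalized to
#' \[0,1\] along each path.
#'
#' @name trajectory
NULL

#' Floyd-Warshall all-pairs shortest paths
#'
#' Dynamic-programming all-pairs shortest paths on the weighted directed
#' population graph. Handles negative edge weights; a negative cycle
#' (negative diagonal after completion) is an error. Ties are broken toward
#' the smaller intermediate population id (intermediates are scanned in
#' ascending order and only strict improvements are taken), so the
#' reconstruction is deterministic.
#'
#' @param g a `population_graph` from [build_knn_graph()].
#' @return A list with `dist` (G-by-G matrix of path costs, `Inf` when
#'   unreachable, 0 on the diagonal), `next_hop` (G-by-G matrix; entry
#'   (s, q) is the node after `s` on a shortest s-to-q path, `NA` when
#'   unreachable), and `ids` (pop_id labelling of the matrix rows).
#' @export
floyd_warshall <- function(g) {
  stopifnot(inherits(g, "population_graph"))
  ids <- g$nodes$pop_id
  G <- length(ids)
  idx <- setNames(seq_len(G), ids)
  dmat <- matrix(Inf, G, G, dimnames = list(ids, ids))
  diag(dmat) <- 0
  nxt <- matrix(NA_integer_, G, G, dimnames = list(ids, ids))
  diag(nxt) <- seq_len(G)
  e <- g$edges
  for (i in seq_len(nrow(e))) {
    s <- idx[[as.character(e$from[i])]]
    q <- idx[[as.character(e$to[i])]]
    if (e$weight[i] < dmat[s, q]) {
      dmat[s, q] <- e$weight[i]
      nxt[s, q] <- q
    }
  }
  for (o in seq_len(G)) {
    through <- outer(dmat[, o], dmat[o, ], "+")
    better <- which(through < dmat, arr.ind = TRUE)
    if (nrow(better) > 0) {
      dmat[better] <- through[better]
      nxt[better] <- nxt[cbind(better[, 1], o)]
    }
  }
  if (any(diag(dmat) < 0)) stop("graph contains a negative cycle", call. = FALSE)
  list(dist = dmat, next_hop = nxt, ids = ids)
}

# ordered pop_id vector for the reconstructed s -> q shortest path
reconstruct_path <- function(fw, s, q) {
  idx <- setNames(seq_along(fw$ids), fw$ids)
  si <- idx[[as.character(s)]]; qi <- idx[[as.character(q)]]
  if (!is.finite(fw$dist[si, qi])) return(NULL)
  path <- si
  guard <- 0L
  while (path[length(path)] != qi) {
    nx <- fw$next_hop[path[length(path)], qi]
    if (is.na(nx)) return(NULL)
    path <- c(path, nx)
    guard <- guard + 1L
    if (guard > length(fw$ids)) stop("path reconstruction cycled", call. = FALSE)
  }
  fw$ids[path]
}

path_edge_weights <- function(g, pop_seq) {
  vapply(seq_len(length(pop_seq) - 1L), function(i) {
    w <- g$edges$weight[g$edges$from == pop_seq[i] & g$edges$to == pop_seq[i + 1]]
    if (length(w) == 0) NA_real_ else min(w)
  }, numeric(1))
}

#' Detect trajectories by greedy path coverage
#'
#' Candidate sources are populations with in-degree 0 (falling back to the
#' minimum observed in-degree); candidate sinks have out-degree 0 (falling
#' back to populations attaining the maximum finite shortest-path distance
#' from any source). Among all reconstructed source-to-sink shortest paths,
#' the path covering the most not-yet-covered populations is selected
#' repeatedly (ties to the lower mean edge weight), until `coverage_target`
#' of the reachable populations are covered or `max_paths` is reached.
#'
#' @param g a `population_graph`.
#' @param fw result of [floyd_warshall()] on `g` (computed when omitted).
#' @param max_paths maximum number of trajectories (default 20).
#' @param coverage_target stop once this fraction of reachable populations
#'   is covered (default 0.95).
#' @return A `trajectory_set` tibble: `path_id`, `source`, `sink`,
#'   `pop_sequence` (list of pop_id vectors), `n_pops`, `total_weight`,
#'   `mean_weight`.
#' @export
detect_trajectories <- function(g, fw = NULL, max_paths = 20L,
                                coverage_target = 0.95) {
  stopifnot(inherits(g, "population_graph"))
  if (nrow(g$edges) == 0) stop("population graph has no edges", call. = FALSE)
  if (is.null(fw)) fw <- floyd_warshall(g)
  ids <- g$nodes$pop_id
  indeg <- table(factor(g$edges$to, levels = ids))
  outdeg <- table(factor(g$edges$from, levels = ids))
  sources <- ids[indeg == 0]
  if (length(sources) == 0) sources <- ids[indeg == min(indeg)]
  sinks <- ids[outdeg == 0]
  if (length(sinks) == 0) {
    dsrc <- fw$dist[as.character(sources), , drop = FALSE]
    finite <- dsrc[is.finite(dsrc)]
    if (length(finite) == 0) stop("no reachable sink from any source", call. = FALSE)
    far <- apply(dsrc, 2L, function(col) {
      f <- col[is.finite(col)]
      if (length(f)) max(f) else -Inf
    })
    sinks <- ids[far == max(far)]
  }
  cand <- list()
  for (s in sources) for (q in sinks) {
    if (s == q) next
    p <- reconstruct_path(fw, s, q)
    if (!is.null(p)) cand[[paste(s, q, sep = "->")]] <- p
  }
  cand <- cand[!duplicated(vapply(cand, paste, character(1), collapse = ","))]
  if (length(cand) == 0) stop("no source-to-sink path found", call. = FALSE)

  reachable <- unique(unlist(cand))
  covered <- integer(0)
  chosen <- list()
  mean_w <- vapply(cand, function(p) mean(path_edge_weights(g, p)), numeric(1))
  len_w <- vapply(cand, length, integer(1))
  while (length(chosen) < max_paths &&
         length(covered) < coverage_target * length(reachable)) {
    gain <- vapply(cand, function(p) length(setdiff(p, covered)), integer(1))
    if (length(gain) == 0 || max(gain) == 0) break
    best <- which(gain == max(gain))
    if (length(best) > 1) best <- best[order(mean_w[best], names(cand)[best])][1]
    chosen[[length(chosen) + 1L]] <- cand[[best]]
    covered <- union(covered, cand[[best]])
    mean_w <- mean_w[-best]; cand <- cand[-best]
  }
  out <- tibble::tibble(
    path_id = seq_along(chosen),
    source = vapply(chosen, function(p) p[1], numeric(1)),
    sink = vapply(chosen, function(p) p[length(p)], numeric(1)),
    pop_sequence = chosen,
    n_pops = vapply(chosen, length, integer(1)),
    total_weight = vapply(chosen, function(p) sum(path_edge_weights(g, p)), numeric(1)),
    mean_weight = vapply(chosen, function(p) mean(path_edge_weights(g, p)), numeric(1)))
  class(out) <- c("trajectory_set", class(out))
  out
}

#' Project a cell onto its population's velocity line
#'
#' The local trajectory through a population is approximated to first order
#' by the line \eqn{W(t) = X^*_s + v_s (t - t_s)}. The cell is mapped to
#' its orthogonal projection \eqn{\hat{x}} on that line; the signed offset
#' \eqn{\delta = (x - X^*_s)\cdot v_s / \lVert v_s\rVert^2} solves
#' \eqn{\hat{x} = W(t_s + \delta)}, so cells ahead of the centroid along
#' the velocity get positive offsets.
#'
#' @param x a cell's expression vector.
#' @param centroid the population centroid \eqn{X^*_s}.
#' @param v_s the population velocity.
#' @return A list with `x_hat` (the projected point) and `delta` (the
#'   signed time offset).
#' @export
project_cell <- function(x, centroid, v_s) {
  nv2 <- sum(v_s^2)
  if (nv2 == 0) stop("population velocity is zero; cannot project", call. = FALSE)
  delta <- sum((x - centroid) * v_s) / nv2
  list(x_hat = centroid + delta * v_s, delta = delta)
}

#' Assign per-cell pseudotime along detected trajectories
#'
#' Populations on a path receive integer times \eqn{t_s = 0, 1, 2, \ldots}
#' by path position. Each member cell's offset \eqn{\delta} (see
#' [project_cell()]) is rescaled within its population to (-0.45, +0.45)
#' by dividing by the population's maximum absolute
#' offset (0 when all offsets vanish), so within-population ordering is
#' preserved while population-level ordering stays authoritative. Raw times
#' \eqn{t_s + \delta'} are then min-max normalized to \[0,1\] per path.
#'
#' @param trajs a `trajectory_set` from [detect_trajectories()] (or a
#'   single-row subset).
#' @param pops the `cell_populations` tibble with velocities filled.
#' @param x cells-by-genes expression matrix (the same space the centroids
#'   live in) or an [expression_dataset()].
#' @return A `cell_times` tibble with one row per (path, cell):
#'   `path_id`, `cell` (row index), `pop_id`, `position` (0-based path
#'   position of the population), `delta`, `raw_time`, `pseudotime`.
#' @export
assign_pseudotime <- function(trajs, pops, x) {
  if (inherits(x, "expression_dataset")) x <- x$spliced
  x <- as.matrix(x)
  vel <- setNames(pops$velocity, pops$pop_id)
  cen <- setNames(pops$centroid, pops$pop_id)
  mem <- setNames(pops$members, pops$pop_id)

  rows <- list()
  for (i in seq_len(nrow(trajs))) {
    seq_ids <- trajs$pop_sequence[[i]]
    path_rows <- list()
    for (pos in seq_along(seq_ids)) {
      pid <- as.character(seq_ids[pos])
      members <- mem[[pid]]
      v_s <- vel[[pid]]; c_s <- cen[[pid]]
      delta <- vapply(members, function(ci)
        project_cell(x[ci, ], c_s, v_s)$delta, numeric(1))
      dmax <- max(abs(delta))
      resc <- if (dmax > 0) 0.45 * delta / dmax else rep(0, length(delta))
      path_rows[[pos]] <- tibble::tibble(
        path_id = trajs$path_id[i], cell = members,
        pop_id = seq_ids[pos], position = pos - 1L,
        delta = delta, raw_time = (pos - 1L) + resc)
    }
    pr <- dplyr::bind_rows(path_rows)
    rng <- range(pr$raw_time)
    pr$pseudotime <- if (diff(rng) > 0) (pr$raw_time - rng[1]) / diff(rng) else 0
    rows[[i]] <- pr
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cell_times", class(out))
  out
}

#' Collapse per-path cell times into one row per cell
#'
#' Each population is attributed to the first path that covers it; a cell's
#' reported pseudotime is taken from that path. Cells in populations not on
#' any selected path get `NA` path and pseudotime.
#'
#' @param times a `cell_times` tibble from [assign_pseudotime()].
#' @param pops the `cell_populations` tibble.
#' @param cell_ids character vector of all cell identifiers.
#' @return A tibble with one row per cell: `cell_id`, `population_id`,
#'   `path_id`, `pseudotime`.
#' @export
cell_time_table <- function(times, pops, cell_ids) {
  first_path <- times |>
    dplyr::group_by(.data$pop_id) |>
    dplyr::summarise(path_id = min(.data$path_id), .groups = "drop")
  keep <- times |>
    dplyr::inner_join(first_path, by = c("pop_id", "path_id"))
  out <- tibble::tibble(cell_id = cell_ids,
                        population_id = population_of_cells(pops, length(cell_ids)),
                        path_id = NA_integer_, pseudotime = NA_real_)
  out$path_id[keep$cell] <- keep$path_id
  out$pseudotime[keep$cell] <- keep$pseudotime
  out
}
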