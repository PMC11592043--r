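#' Refine mixture clusters into cell populations
#'
#' A cell population (CP) is a small sub-cluster of one mixture component,
#' used as the working unit for velocity smoothing, graph construction and
#' path finding — conceptually a metacell. Each cluster of `model` is split
#' by seeded k-means into `max(1, round(size / target_pop_size))` CPs, so
#' the CP count scales with cluster size. Population ids are assigned
#' deterministically: sorted by parent cluster, then by the smallest member
#' index within the cluster.
#'
#' @param x cells-by-genes matrix or [expression_dataset()] (spliced layer).
#' @param model a fitted `mixture_model` (see [fit_gmm()]), or any integer
#'   vector of per-cell cluster assignments.
#' @param target_pop_size desired cells per CP (default 20).
#' @param seed integer seed for the within-cluster k-means.
#' @return A `cell_populations` tibble with one row per CP and columns
#'   `pop_id`, `parent_cluster`, `n_cells`, `members` (list of cell row
#'   indices), `centroid` (list of numeric vectors), `velocity` (list,
#'   `NULL` until filled by [smooth_population_velocities()]).
#' @export
refine_clusters <- function(x, model, target_pop_size = 20, seed = 1L) {
  if (inherits(x, "expression_dataset")) x <- x$spliced
  x <- as.matrix(x)
  if (target_pop_size < 1) stop("target_pop_size must be >= 1", call. = FALSE)
  assignments <- if (inherits(model, "mixture_model")) model$assignments else as.integer(model)
  if (length(assignments) != nrow(x))
    stop("assignments must have one entry per cell", call. = FALSE)

  pieces <- list()
  for (k in sort(unique(assignments))) {
    idx <- which(assignments == k)
    if (length(idx) == 0) {
      warning(sprintf("cluster %d is empty; skipped", k))
      next
    }
    s_k <- max(1L, as.integer(round(length(idx) / target_pop_size)))
    sub <- split_cluster(x[idx, , drop = FALSE], s_k, seed = derive_seed(seed, k))
    for (grp in sub) {
      members <- idx[grp]
      pieces[[length(pieces) + 1L]] <- list(
        parent_cluster = k,
        members = members,
        centroid = colMeans(x[members, , drop = FALSE]))
    }
  }
  ord <- order(vapply(pieces, function(p) p$parent_cluster, numeric(1)),
               vapply(pieces, function(p) min(p$members), numeric(1)))
  pieces <- pieces[ord]
  tibble::tibble(
    pop_id = seq_along(pieces),
    parent_cluster = vapply(pieces, function(p) as.integer(p$parent_cluster), integer(1)),
    n_cells = vapply(pieces, function(p) length(p$members), integer(1)),
    members = lapply(pieces, function(p) p$members),
    centroid = lapply(pieces, function(p) p$centroid),
    velocity = rep(list(NULL), length(pieces))
  ) -> pops
  class(pops) <- c("cell_populations", class(pops))
  pops
}

# partition the rows of xk into s groups; k-means when the geometry allows it,
# balanced index slicing when there are fewer distinct points than groups
split_cluster <- function(xk, s, seed) {
  mk <- nrow(xk)
  if (s <= 1 || mk <= s) {
    if (s <= 1) return(list(seq_len(mk)))
    return(split(seq_len(mk), rep(seq_len(s), length.out = mk)))
  }
  distinct <- nrow(unique(xk))
  if (distinct < s) {
    return(split(seq_len(mk), sort(rep(seq_len(s), length.out = mk))))
  }
  fit <- with_seed(seed, kmeans(xk, centers = s, nstart = 5, iter.max = 50))
  split(seq_len(mk), fit$cluster)
}

# cells-by-1 tibble mapping each cell to its population (NA when unassigned)
population_of_cells <- function(pops, m) {
  out <- rep(NA_integer_, m)
  for (i in seq_len(nrow(pops))) out[pops$members[[i]]] <- pops$pop_id[i]
  out
}

centroid_matrix <- function(pops) {
  do.call(rbind, pops$centroid)
}

velocity_matrix <- function(pops) {
  if (any(vapply(pops$velocity, is.null, logical(1))))
    stop("population velocities not filled; run smooth_population_velocities() first",
         call. = FALSE)
  do.call(rbind, pops$velocity)
}
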