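test_that("Floyd-Warshall handles chains, unreachable pairs and negative edges", {
  # a -> b -> c chain
  g <- make_pop_graph(edge_tbl(c(1, 2), c(2, 3), c(1, 1)), 3)
  fw <- floyd_warshall(g)
  expect_equal(fw$dist[1, 3], 2)
  expect_equal(poptraj:::reconstruct_path(fw, 1, 3), c(1, 2, 3))
  # unreachable pair
  expect_equal(fw$dist[3, 1], Inf)
  expect_true(is.na(fw$next_hop[3, 1]))
  expect_equal(diag(fw$dist), setNames(rep(0, 3), 1:3))

  # 4-node digraph with a negative shortcut vs exhaustive enumeration
  e <- edge_tbl(c(1, 1, 2, 3, 2), c(2, 3, 4, 4, 3), c(2, 5, 4, -1, 1))
  gn <- make_pop_graph(e, 4)
  fwn <- floyd_warshall(gn)
  for (s in 1:4) for (q in 1:4) {
    if (s == q) next
    expect_equal(fwn$dist[s, q], enumerate_shortest(e, 4, s, q))
  }

  # negative cycle detection
  bad <- make_pop_graph(edge_tbl(c(1, 2), c(2, 1), c(1, -3)), 2)
  expect_error(floyd_warshall(bad), "negative cycle")
})

test_that("Floyd-Warshall agrees with Dijkstra on random positive digraphs", {
  set.seed(13)
  for (rep in 1:20) {
    G <- sample(4:9, 1)
    ne <- sample(G:(G * (G - 1)), 1)
    pairs <- expand.grid(from = 1:G, to = 1:G)
    pairs <- pairs[pairs$from != pairs$to, ]
    pick <- pairs[sample(nrow(pairs), min(ne, nrow(pairs))), ]
    e <- edge_tbl(pick$from, pick$to, runif(nrow(pick), 0.1, 5))
    fw <- floyd_warshall(make_pop_graph(e, G))
    for (s in 1:G) {
      expect_equal(unname(fw$dist[s, ]), dijkstra_dist(e, G, s))
    }
    # triangle inequality holds for every triple after completion
    d <- fw$dist
    for (o in 1:G) expect_true(all(d <= outer(d[, o], d[o, ], "+") + 1e-12))
  }
})

test_that("trajectory detection covers chains and bifurcations", {
  chain <- make_pop_graph(edge_tbl(1:4, 2:5, rep(1, 4)), 5)
  trajs <- detect_trajectories(chain)
  expect_equal(nrow(trajs), 1)
  expect_equal(trajs$pop_sequence[[1]], 1:5)

  # one source, two sinks sharing a trunk
  bif <- make_pop_graph(
    edge_tbl(c(1, 2, 3, 3, 4, 6), c(2, 3, 4, 6, 5, 7), rep(1, 6)), 7)
  t2 <- detect_trajectories(bif)
  expect_equal(nrow(t2), 2)
  seqs <- t2$pop_sequence
  expect_setequal(vapply(seqs, function(p) p[length(p)], numeric(1)), c(5, 7))
  expect_true(all(vapply(seqs, function(p) all(p[1:3] == 1:3), logical(1))))

  # max_paths = 1 keeps the single best-covering path
  t1 <- detect_trajectories(bif, max_paths = 1)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$n_pops[1], 5)

  expect_error(detect_trajectories(make_pop_graph(edge_tbl(integer(0),
    integer(0), numeric(0)), 2)), "no edges")
})

test_that("cell projection onto the velocity line matches hand computation", {
  # x at the centroid projects to the centroid with zero offset
  p0 <- project_cell(c(1, 2), c(1, 2), c(3, 0))
  expect_equal(p0$x_hat, c(1, 2))
  expect_equal(p0$delta, 0)
  # one full velocity step ahead
  p1 <- project_cell(c(1, 2) + c(3, 0), c(1, 2), c(3, 0))
  expect_equal(p1$delta, 1)
  # 2-D worked example: centroid origin, v = (1,0), x = (2,5)
  p2 <- project_cell(c(2, 5), c(0, 0), c(1, 0))
  expect_equal(p2$x_hat, c(2, 0))
  expect_equal(p2$delta, 2)
  expect_error(project_cell(c(1, 1), c(0, 0), c(0, 0)), "zero")
})

test_that("pseudotime assignment reproduces the six-cell worked example", {
  fx <- six_cell_fixture()
  times <- assign_pseudotime(fx$trajs, fx$pops, fx$x)
  times <- times[order(times$cell), ]
  # offsets: CP1 (-0.1, 0.1) -> +-0.45; CP2 (-0.2, 0.1) -> (-0.45, 0.225);
  # CP3 (-0.05, 0.3) -> (-0.075, 0.45); raw = position + rescaled offset
  raw <- c(-0.45, 0.45, 1 - 0.45, 1 + 0.225, 2 - 0.075, 2 + 0.45)
  expect_equal(times$raw_time, raw)
  expect_equal(times$pseudotime, (raw + 0.45) / 2.9)
  # full ordering matches the cells' true 1-D positions
  expect_equal(order(times$pseudotime), order(fx$x[, 1]))
  # endpoints attained
  expect_equal(min(times$pseudotime), 0)
  expect_equal(max(times$pseudotime), 1)
})

test_that("pseudotime is order-preserving within populations and bounded", {
  fx <- six_cell_fixture()
  times <- assign_pseudotime(fx$trajs, fx$pops, fx$x)
  expect_true(all(times$pseudotime >= 0 & times$pseudotime <= 1))
  by_pop <- split(times, times$pop_id)
  for (tp in by_pop) {
    expect_equal(order(tp$delta), order(tp$pseudotime))
  }
  # degenerate: all cells exactly at centroids -> times are path positions
  xc <- matrix(c(0, 0, 1, 1, 2, 2), 6, 1)
  tc <- assign_pseudotime(fx$trajs, fx$pops, xc)
  expect_equal(sort(unique(tc$pseudotime)), c(0, 0.5, 1))
})

test_that("per-cell table attributes shared populations to the first path", {
  fx <- six_cell_fixture()
  # two paths sharing population 1
  trajs2 <- tibble::tibble(path_id = 1:2, source = 1, sink = c(3, 2),
                           pop_sequence = list(c(1, 3), c(1, 2)),
                           n_pops = 2L, total_weight = NA_real_,
                           mean_weight = NA_real_)
  times <- assign_pseudotime(trajs2, fx$pops, fx$x)
  tab <- cell_time_table(times, fx$pops, paste0("c", 1:6))
  expect_equal(tab$path_id, c(1L, 1L, 2L, 2L, 1L, 1L))
  expect_true(all(!is.na(tab$pseudotime)))
  expect_equal(tab$population_id, c(1L, 1L, 2L, 2L, 3L, 3L))
})
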