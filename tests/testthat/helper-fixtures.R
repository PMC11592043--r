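# fixtures and independent oracles shared across test files

# tiny dataset with exact values (dyadic so text round trips are lossless)
toy_dataset <- function(m = 3, n = 2, seed = 42) {
  set.seed(seed)
  rmat <- function() matrix(round(rnorm(m * n), 4), m, n)
  expression_dataset(abs(rmat()), abs(rmat()), rmat(),
                     cell_ids = paste0("c", seq_len(m)),
                     gene_ids = paste0("g", seq_len(n)))
}

# build a population_graph skeleton from an explicit edge table
make_pop_graph <- function(edges, n_nodes) {
  structure(
    list(nodes = tibble::tibble(pop_id = seq_len(n_nodes)),
         edges = edges, k = NA, lambda = NA, beta = NA, d_max = NA),
    class = "population_graph")
}

edge_tbl <- function(from, to, weight) {
  tibble::tibble(from = from, to = to, dist = NA_real_,
                 l_alpha = NA_real_, l_d = NA_real_, weight = weight)
}

# independent Dijkstra oracle (non-negative weights only)
dijkstra_dist <- function(edges, n_nodes, source) {
  dist <- rep(Inf, n_nodes)
  dist[source] <- 0
  visited <- rep(FALSE, n_nodes)
  repeat {
    cand <- which(!visited & is.finite(dist))
    if (length(cand) == 0) break
    u <- cand[which.min(dist[cand])]
    visited[u] <- TRUE
    out <- edges[edges$from == u, ]
    for (j in seq_len(nrow(out))) {
      v <- out$to[j]
      if (dist[u] + out$weight[j] < dist[v]) dist[v] <- dist[u] + out$weight[j]
    }
  }
  dist
}

# exhaustive simple-path oracle for small digraphs (handles negative edges)
enumerate_shortest <- function(edges, n_nodes, s, q) {
  best <- Inf
  recurse <- function(node, visited, cost) {
    if (node == q) {
      best <<- min(best, cost)
      return()
    }
    out <- edges[edges$from == node, ]
    for (j in seq_len(nrow(out))) {
      v <- out$to[j]
      if (!(v %in% visited)) recurse(v, c(visited, v), cost + out$weight[j])
    }
  }
  recurse(s, s, 0)
  best
}

# a hand-checkable 3-population chain with two cells per population
six_cell_fixture <- function() {
  x <- matrix(c(-0.1, 0.1, 0.8, 1.1, 1.95, 2.3), 6, 1)
  pops <- tibble::tibble(
    pop_id = 1:3, parent_cluster = 1L, n_cells = 2L,
    members = list(1:2, 3:4, 5:6),
    centroid = list(0, 1, 2),
    velocity = list(1, 1, 1))
  trajs <- tibble::tibble(path_id = 1L, source = 1, sink = 3,
                          pop_sequence = list(1:3), n_pops = 3L,
                          total_weight = NA_real_, mean_weight = NA_real_)
  list(x = x, pops = pops, trajs = trajs)
}

# brute-force pair-counting oracles for the rank metrics
naive_tau_b_abs <- function(pred, true) {
  m <- length(pred)
  C <- 0; D <- 0; tp <- 0; tt <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    a <- pred[i] - pred[j]; b <- true[i] - true[j]
    if (a == 0 && b == 0) next
    else if (a == 0) tp <- tp + 1
    else if (b == 0) tt <- tt + 1
    else if (sign(a) == sign(b)) C <- C + 1
    else D <- D + 1
  }
  abs(C - D) / sqrt((C + D + tp) * (C + D + tt))
}

naive_spearman <- function(pred, true) {
  rp <- rank(pred); rt <- rank(true)
  m <- length(pred)
  num <- sum((rt - mean(rt)) * (rp - mean(rp)))
  num / sqrt(sum((rt - mean(rt))^2) * sum((rp - mean(rp))^2))
}

# dense direct implementation of the GP posterior (no Cholesky reuse)
naive_gp_posterior <- function(inputs, targets, query, sigma, l, sigma_rbf) {
  mu_v <- colMeans(as.matrix(targets))
  yc <- sweep(as.matrix(targets), 2, mu_v)
  K <- rbf_kernel(inputs, inputs, l, sigma_rbf) + diag(sigma^2, nrow(inputs))
  Ks <- rbf_kernel(query, inputs, l, sigma_rbf)
  Kss <- rbf_kernel(query, query, l, sigma_rbf)
  mean <- sweep(Ks %*% solve(K, yc), 2, mu_v, "+")
  cov <- Kss + diag(sigma^2, nrow(query)) - Ks %*% solve(K, t(Ks))
  list(mean = mean, variance = diag(cov))
}

# direct-density responsibility oracle for small mixtures
naive_responsibilities <- function(x, weights, means, variances) {
  m <- nrow(x); K <- length(weights)
  gamma <- matrix(0, m, K)
  for (i in seq_len(m)) for (k in seq_len(K)) {
    gamma[i, k] <- weights[k] *
      prod(stats::dnorm(x[i, ], means[k, ], sqrt(variances[k, ])))
  }
  gamma / rowSums(gamma)
}
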