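test_that("generation is reproducible and validates its spec", {
  spec <- topology_spec("bifurcating", n_cells = 80, n_genes = 12,
                        noise_sd = 0.1, seed = 5)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$spliced, d2$spliced)
  expect_identical(d1$unspliced, d2$unspliced)
  expect_identical(d1$velocity, d2$velocity)
  expect_identical(d1$truth_time, d2$truth_time)

  other <- generate_dataset(topology_spec("bifurcating", 80, 12, 0.1, seed = 6))
  expect_false(identical(d1$spliced, other$spliced))

  expect_error(topology_spec("linear", n_cells = 10), "n_cells")
  expect_error(topology_spec("linear", n_genes = 2), "n_genes")
  expect_error(topology_spec("spiral"), "arg")
})

test_that("branch labels partition cells with reasonable branch sizes", {
  for (kind in c("linear", "bifurcating", "trifurcating", "cycletree")) {
    ds <- generate_dataset(topology_spec(kind, n_cells = 500, n_genes = 10,
                                         noise_sd = 0.05, seed = 1))
    expect_equal(length(ds$truth_branch), 500)
    expect_true(all(table(ds$truth_branch) >= 10))
    n_branches <- length(unique(ds$truth_branch))
    want <- c(linear = 1, bifurcating = 3, trifurcating = 4, cycletree = 5)
    expect_equal(n_branches, unname(want[kind]))
    expect_true(all(ds$truth_time >= 0 & ds$truth_time <= 1))
  }
})

test_that("velocity is the analytic derivative of expression along time", {
  ds <- generate_dataset(topology_spec("linear", n_cells = 3000, n_genes = 10,
                                       noise_sd = 0, seed = 2))
  ord <- order(ds$truth_time)
  t_sorted <- ds$truth_time[ord]
  for (g in c(1, 5, 10)) {
    s <- ds$spliced[ord, g]
    v <- ds$velocity[ord, g]
    # second-order non-uniform central differences on interior cells
    i <- 2:(length(s) - 1)
    h1 <- t_sorted[i + 1] - t_sorted[i]
    h2 <- t_sorted[i] - t_sorted[i - 1]
    fd <- (h2^2 * s[i + 1] + (h1^2 - h2^2) * s[i] - h1^2 * s[i - 1]) /
      (h1 * h2 * (h1 + h2))
    expect_lt(max(abs(fd - v[i])) / max(abs(v)), 1e-3)
  }
})

test_that("cycle programs are exactly periodic in the cycle phase", {
  set.seed(23)
  progs <- poptraj:::draw_cycle_programs(5)
  for (p in progs) {
    expect_equal(poptraj:::cycle_value(p, 0), poptraj:::cycle_value(p, 1),
                 tolerance = 1e-12)
  }
  # and so are derivatives: integrating once around the cycle returns home
  for (p in progs) {
    expect_equal(poptraj:::cycle_deriv(p, 0, 0.25),
                 poptraj:::cycle_deriv(p, 1, 0.25), tolerance = 1e-12)
  }
})

test_that("unspliced layer is non-negative and obeys the kinetic relation", {
  ds <- generate_dataset(topology_spec("bifurcating", n_cells = 300,
                                       n_genes = 15, noise_sd = 0.05, seed = 7))
  expect_true(all(ds$unspliced >= 0))
  kin <- attr(ds, "kinetics")
  # v = beta * u - gamma * s wherever clipping did not bite
  u_raw <- sweep(ds$velocity + sweep(ds$spliced, 2, kin$gamma, "*"),
                 2, kin$beta, "/")
  unclipped <- u_raw > 0
  v_back <- sweep(ds$unspliced, 2, kin$beta, "*") -
    sweep(ds$spliced, 2, kin$gamma, "*")
  expect_equal(ds$velocity[unclipped], v_back[unclipped], tolerance = 1e-10)
})

test_that("self-comparison of truth time scores perfectly", {
  ds <- generate_dataset(topology_spec("linear", n_cells = 100, n_genes = 10,
                                       noise_sd = 0.1, seed = 4))
  expect_equal(kendall_tau_b_abs(ds$truth_time, ds$truth_time), 1)
  expect_equal(spearman_rho(ds$truth_time, ds$truth_time), 1)
})
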