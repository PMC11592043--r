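test_that("diagonal Gaussian log-density matches closed forms", {
  expect_equal(gmm_log_density(0, 0, 1), log(1 / sqrt(2 * pi)))
  # at the mode the quadratic term vanishes
  s2 <- c(0.3, 2.5)
  expect_equal(gmm_log_density(c(1, -2), c(1, -2), s2),
               -0.5 * sum(log(2 * pi * s2)))
  # hand-evaluated 1-D case: x = 2, mu = 0, variance 4
  expect_equal(gmm_log_density(2, 0, 4), -0.5 * (log(8 * pi) + 1))
  expect_error(gmm_log_density(0, 0, 0), "positive")
})

test_that("E-step posteriors match symmetry and direct evaluation", {
  x <- matrix(rnorm(10), 5, 2)
  one <- list(weights = 1, means = matrix(0, 1, 2), variances = matrix(1, 1, 2))
  expect_equal(gmm_e_step(x, one), matrix(1, 5, 1))

  # mirror-symmetric components about the observation
  sym <- list(weights = c(0.5, 0.5), means = matrix(c(-1, 1), 2, 1),
              variances = matrix(1, 2, 1))
  expect_equal(gmm_e_step(matrix(0), sym), matrix(0.5, 1, 2))

  # 1-D, N(0,1) vs N(4,1), equal weights, x = 1: gamma_1 = 1/(1+exp(-4))
  mod <- list(weights = c(0.5, 0.5), means = matrix(c(0, 4), 2, 1),
              variances = matrix(1, 2, 1))
  g <- gmm_e_step(matrix(1), mod)
  expect_equal(g[1, 1], 1 / (1 + exp(-4)), tolerance = 1e-12)
})

test_that("E-step matches a direct-density oracle on small instances", {
  set.seed(11)
  for (rep in 1:5) {
    m <- sample(5:50, 1); n <- sample(1:3, 1); K <- sample(1:3, 1)
    x <- matrix(rnorm(m * n), m, n)
    w <- runif(K); w <- w / sum(w)
    mu <- matrix(rnorm(K * n), K, n)
    s2 <- matrix(runif(K * n, 0.5, 2), K, n)
    model <- list(weights = w, means = mu, variances = s2)
    expect_equal(gmm_e_step(x, model), naive_responsibilities(x, w, mu, s2),
                 tolerance = 1e-10)
  }
})

test_that("M-step recovers weighted means and variances", {
  x <- matrix(c(0, 1, 4, 5), 4, 1)
  g <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2)
  up <- gmm_m_step(x, g)
  expect_equal(up$weights, c(0.5, 0.5))
  expect_equal(as.vector(up$means), c(0.5, 4.5))
  expect_equal(as.vector(up$variances), c(0.25, 0.25), tolerance = 1e-5)

  # uniform responsibilities collapse all means onto the global mean
  xu <- matrix(rnorm(12), 6, 2)
  gu <- matrix(1 / 3, 6, 3)
  upu <- gmm_m_step(xu, gu)
  expect_equal(upu$means, matrix(colMeans(xu), 3, 2, byrow = TRUE))
})

test_that("EM fits: K=1 closed form, blob recovery, monotone likelihood", {
  set.seed(5)
  x <- matrix(rnorm(60), 30, 2)
  f1 <- fit_gmm(x, K = 1, seed = 1)
  expect_equal(as.vector(f1$means), colMeans(x))
  pop_var <- colMeans(sweep(x, 2, colMeans(x))^2)
  expect_equal(as.vector(f1$variances), pop_var + 1e-6, tolerance = 1e-8)
  expect_equal(f1$weights, 1)

  # two well-separated 1-D blobs are recovered exactly up to labels
  xb <- matrix(c(rnorm(50, -10), rnorm(50, 10)), ncol = 1)
  fb <- fit_gmm(xb, K = 2, seed = 7)
  truth <- rep(1:2, each = 50)
  agreement <- max(mean(fb$assignments == truth),
                   mean(fb$assignments == 3 - truth))
  expect_equal(agreement, 1)

  # log-likelihood trace never decreases (EM guarantee), over seeds
  ds <- generate_dataset(topology_spec("bifurcating", n_cells = 80,
                                       n_genes = 10, noise_sd = 0.2, seed = 2))
  for (s in 1:5) {
    f <- fit_gmm(ds$spliced, K = 3, seed = s, max_iter = 40)
    expect_true(all(diff(f$log_likelihood_trace) >= -1e-8))
  }
  expect_error(fit_gmm(x, K = 31), "outside")
})

test_that("responsibility rows always sum to one", {
  ds <- generate_dataset(topology_spec("trifurcating", n_cells = 90,
                                       n_genes = 12, noise_sd = 0.3, seed = 9))
  f <- fit_gmm(ds$spliced, K = 4, seed = 3)
  expect_equal(rowSums(f$responsibilities), rep(1, 90), tolerance = 1e-10)
})

test_that("relabelling mixture components leaves the partition unchanged", {
  set.seed(21)
  x <- matrix(rnorm(80), 40, 2)
  f <- fit_gmm(x, K = 3, seed = 4)
  perm <- c(3, 1, 2)
  permuted <- list(weights = f$weights[perm], means = f$means[perm, ],
                   variances = f$variances[perm, ])
  z1 <- max.col(gmm_e_step(x, f))
  z2 <- max.col(gmm_e_step(x, permuted))
  # same partition: the contingency table has one nonzero entry per row/col
  tab <- table(z1, z2)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("BIC selection returns singleton ranges and prefers K=1 on one Gaussian", {
  set.seed(3)
  x <- matrix(rnorm(40), 20, 2)
  expect_equal(select_K(x, K_range = 3, seed = 1)$K, 3)
  expect_error(select_K(x, K_range = integer(0)), "empty")

  picks <- vapply(1:20, function(r) {
    xr <- matrix(rnorm(120), 60, 2)
    select_K(xr, K_range = 1:4, seed = r)$K
  }, numeric(1))
  expect_gt(mean(picks == 1), 0.5)

  sel <- select_K(x, K_range = 1:3, seed = 1)
  expect_named(sel$bic, c("K", "log_likelihood", "bic"))
  expect_equal(nrow(sel$bic), 3)
})
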