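test_that("RBF kernel matches hand-evaluated entries and limits", {
  a <- matrix(c(0, 1), 2, 1)
  expect_equal(rbf_kernel(a, a, l = 1, sigma_rbf = 2)[1, 1], 4)
  expect_equal(rbf_kernel(matrix(0), matrix(2), l = 1, sigma_rbf = 1)[1, 1],
               exp(-2))
  expect_lt(rbf_kernel(matrix(0), matrix(1e4), l = 1, sigma_rbf = 1)[1, 1],
            1e-300)
  expect_error(rbf_kernel(a, a, l = 0, sigma_rbf = 1), "positive")
})

test_that("posterior matches a dense direct implementation", {
  # the worked 2-point case: (0 -> 0), (2 -> 1), query at 1
  tr_x <- matrix(c(0, 2), 2, 1); tr_y <- matrix(c(0, 1), 2, 1)
  model <- gpr_model(tr_x, tr_y, sigma = 0.1, l = 1, sigma_rbf = 1)
  got <- predict(model, matrix(1))
  want <- naive_gp_posterior(tr_x, tr_y, matrix(1), 0.1, 1, 1)
  expect_equal(got$mean, want$mean, tolerance = 1e-10)

  # up to 10 random training points, several queries, mean and variance
  set.seed(8)
  for (rep in 1:5) {
    p <- sample(3:10, 1); d <- sample(1:3, 1)
    X <- matrix(rnorm(p * d), p, d)
    Y <- matrix(rnorm(p * 2), p, 2)
    Q <- matrix(rnorm(4 * d), 4, d)
    sig <- runif(1, 0.05, 0.5); ll <- runif(1, 0.5, 2); sr <- runif(1, 0.5, 2)
    model <- gpr_model(X, Y, sigma = sig, l = ll, sigma_rbf = sr)
    got <- predict(model, Q)
    want <- naive_gp_posterior(X, Y, Q, sig, ll, sr)
    expect_equal(got$mean, want$mean, tolerance = 1e-8)
    expect_equal(got$variance, want$variance, tolerance = 1e-8)
  }
})

test_that("noise-free GP interpolates training targets exactly", {
  set.seed(2)
  X <- matrix(runif(6, 0, 3), 6, 1)
  Y <- matrix(sin(X), 6, 1)
  model <- gpr_model(X, Y, sigma = 0, l = 1, sigma_rbf = 1)
  got <- predict(model, X)
  expect_equal(as.vector(got$mean), as.vector(Y), tolerance = 1e-6)
})

test_that("far queries revert to the prior mean and variance stays non-negative", {
  set.seed(3)
  X <- matrix(rnorm(8), 8, 1)
  Y <- matrix(rnorm(16), 8, 2)
  model <- gpr_model(X, Y, sigma = 0.2, l = 0.7, sigma_rbf = 1.5)
  far <- predict(model, matrix(1e3))
  expect_equal(as.vector(far$mean), colMeans(Y), tolerance = 1e-6)
  everywhere <- predict(model, matrix(seq(-5, 5, length.out = 50)))
  expect_true(all(everywhere$variance >= 0))
})

test_that("predictions are invariant to permuting the training points", {
  set.seed(4)
  X <- matrix(rnorm(14), 7, 2)
  Y <- matrix(rnorm(7), 7, 1)
  Q <- matrix(rnorm(6), 3, 2)
  perm <- sample(7)
  m1 <- gpr_model(X, Y, 0.3, 1.2, 1)
  m2 <- gpr_model(X[perm, ], Y[perm, , drop = FALSE], 0.3, 1.2, 1)
  expect_equal(predict(m1, Q)$mean, predict(m2, Q)$mean, tolerance = 1e-10)
})

test_that("growing noise shrinks the posterior mean toward the prior mean", {
  X <- matrix(c(-1, 0, 1, 2), 4, 1)
  Y <- matrix(c(2, 1, 3, 4), 4, 1)
  q <- matrix(0.5)
  prior <- mean(Y)
  dev <- vapply(c(0.01, 0.1, 0.5, 2, 10), function(s) {
    abs(predict(gpr_model(X, Y, s, 1, 1), q)$mean[1, 1] - prior)
  }, numeric(1))
  expect_true(all(diff(dev) <= 1e-12))
})

test_that("marginal-likelihood fitting recovers a noiseless sine", {
  set.seed(6)
  X <- matrix(seq(0, 2 * pi, length.out = 10), 10, 1)
  Y <- matrix(sin(X), 10, 1)
  fit <- fit_gpr(X, Y, restarts = 3, seed = 1)
  held <- matrix(seq(0.3, 2 * pi - 0.3, length.out = 40), ncol = 1)
  pred <- predict(fit, held)$mean
  rmse <- sqrt(mean((pred - sin(held))^2))
  expect_lt(rmse, 0.05)

  # contradictory duplicated points force noise strictly above its floor
  Xd <- matrix(c(0, 0, 1, 2), 4, 1)
  Yd <- matrix(c(-1, 1, 0, 0.5), 4, 1)
  fitd <- fit_gpr(Xd, Yd, restarts = 3, seed = 1)
  expect_gt(fitd$sigma, 1e-4 * sd(Yd) * 1.01)

  # zero targets: no signal, posterior mean identically zero
  fit0 <- fit_gpr(matrix(1:5, 5, 1), matrix(0, 5, 1), restarts = 2, seed = 1)
  expect_equal(as.vector(predict(fit0, matrix(c(1.5, 3.3)))$mean), c(0, 0),
               tolerance = 1e-8)
  expect_error(fit_gpr(matrix(1), matrix(1)), "at least 2")
})

test_that("population velocity smoothing honours constant and linear fields", {
  set.seed(9)
  # constant velocity within a cluster is reproduced at every population
  m <- 40
  x <- matrix(rnorm(m * 2), m, 2)
  v <- matrix(rep(c(1.5, -2), each = m), m, 2)
  ds <- expression_dataset(x, x, v)
  pops <- refine_clusters(x, rep(1L, m), target_pop_size = 10, seed = 1)
  pops <- smooth_population_velocities(ds, pops, seed = 1)
  for (i in seq_len(nrow(pops))) {
    expect_equal(pops$velocity[[i]], c(1.5, -2), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }

  # linear field v = 2x on a 1-D cluster: prediction close to 2 * centroid
  x1 <- matrix(seq(-2, 2, length.out = 60), ncol = 1)
  v1 <- 2 * x1
  ds1 <- expression_dataset(x1, x1, v1)
  pops1 <- refine_clusters(x1, rep(1L, 60), target_pop_size = 15, seed = 2)
  pops1 <- smooth_population_velocities(ds1, pops1, seed = 2)
  for (i in seq_len(nrow(pops1))) {
    expect_equal(pops1$velocity[[i]], 2 * pops1$centroid[[i]], tolerance = 0.1,
                 ignore_attr = TRUE)
  }

  # global mode fills velocities too
  pops_g <- smooth_population_velocities(ds, refine_clusters(x, rep(1L, m), 10, 1),
                                         mode = "global", seed = 3)
  expect_true(all(!vapply(pops_g$velocity, is.null, logical(1))))
})
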