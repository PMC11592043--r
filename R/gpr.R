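#' Gaussian-process regression for population velocity smoothing
#'
#' A GP prior with RBF kernel is placed on the map from expression space to
#' velocity; observed (cell expression, cell velocity) pairs condition the
#' posterior, which is then evaluated at cell-population centroids. Output
#' dimensions (genes) are treated as independent GPs sharing one kernel and
#' one noise level, so a single Cholesky factor is reused across genes.
#'
#' @name gpr
NULL

#' RBF (Gaussian) kernel matrix
#'
#' Entry (i, j) is \eqn{\sigma_{RBF}^2 \exp(-\lVert a_i - b_j\rVert^2 / 2\ell^2)}.
#'
#' @param a,b numeric matrices with `d` columns (rows are points).
#' @param l length-scale, `> 0`.
#' @param sigma_rbf signal scale, `> 0`.
#' @return A `nrow(a)` by `nrow(b)` kernel matrix.
#' @export
rbf_kernel <- function(a, b, l, sigma_rbf) {
  if (l <= 0 || sigma_rbf <= 0)
    stop("kernel hyperparameters must be strictly positive", call. = FALSE)
  sigma_rbf^2 * exp(-pairwise_sqdist(a, b) / (2 * l^2))
}

gpr_chol <- function(Kmat, jitter = 1e-8) {
  p <- nrow(Kmat)
  for (j in c(0, jitter, 1e-6, 1e-4)) {
    L <- tryCatch(t(chol(Kmat + diag(j, p))), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  stop("covariance matrix is not positive definite even after jitter escalation",
       call. = FALSE)
}

# negative sum over outputs of the GP log marginal likelihood at
# log-parameters theta = (log sigma, log l, log sigma_rbf)
gpr_nll <- function(theta, inputs, targets_centered) {
  sigma <- exp(theta[1]); l <- exp(theta[2]); s_rbf <- exp(theta[3])
  p <- nrow(inputs)
  Kmat <- rbf_kernel(inputs, inputs, l, s_rbf) + diag(sigma^2, p)
  L <- tryCatch(t(chol(Kmat + diag(1e-10, p))), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(t(L), forwardsolve(L, targets_centered))
  logdet <- 2 * sum(log(diag(L)))
  n_out <- ncol(targets_centered)
  0.5 * sum(targets_centered * alpha) +
    0.5 * n_out * (logdet + p * log(2 * pi))
}

#' Fit GP hyperparameters by marginal likelihood
#'
#' Maximizes the log marginal likelihood of the per-output-centered targets
#' over \eqn{\xi = (\sigma, \ell, \sigma_{RBF})} (noise scale, length-scale,
#' signal scale) by multi-start L-BFGS-B in log-parameter space. Bounds
#' default to \eqn{\ell \in [10^{-2}, 10^3] \cdot} median pairwise training
#' distance and \eqn{\sigma, \sigma_{RBF} \in [10^{-4}, 10^3] \cdot} target
#' standard deviation.
#'
#' @param inputs numeric matrix of training points (rows).
#' @param targets numeric matrix (or vector) of training targets; columns
#'   are independent outputs.
#' @param init optional initial `c(sigma, l, sigma_rbf)`.
#' @param bounds optional list with `sigma`, `l`, `sigma_rbf`, each a
#'   positive `c(lower, upper)`.
#' @param restarts number of random restarts beyond the initial point.
#' @param seed integer seed for the restarts.
#' @return A `gpr_model`: list with `inputs`, `targets`, `target_means`,
#'   `sigma`, `l`, `sigma_rbf`, `L` (lower Cholesky of `K + sigma^2 I`),
#'   `alpha` (`(K + sigma^2 I)^{-1} (targets - means)`), `nll`.
#' @export
fit_gpr <- function(inputs, targets, init = NULL, bounds = NULL,
                    restarts = 3L, seed = 1L) {
  inputs <- as.matrix(inputs)
  targets <- as.matrix(targets)
  p <- nrow(inputs)
  if (p < 2) stop("need at least 2 training points", call. = FALSE)
  if (anyNA(inputs) || anyNA(targets) ||
      any(!is.finite(inputs)) || any(!is.finite(targets)))
    stop("training data contain non-finite values", call. = FALSE)

  mu_v <- colMeans(targets)
  yc <- sweep(targets, 2L, mu_v)

  d_med <- median(dist(inputs))
  if (!is.finite(d_med) || d_med <= 0) d_med <- 1
  y_sd <- sd(as.vector(yc))
  if (!is.finite(y_sd) || y_sd <= 0) y_sd <- 1e-8
  if (is.null(bounds)) {
    bounds <- list(sigma = c(1e-4, 1e3) * y_sd,
                   l = c(1e-2, 1e3) * d_med,
                   sigma_rbf = c(1e-4, 1e3) * y_sd)
  }
  lower <- log(c(bounds$sigma[1], bounds$l[1], bounds$sigma_rbf[1]))
  upper <- log(c(bounds$sigma[2], bounds$l[2], bounds$sigma_rbf[2]))
  if (is.null(init)) init <- c(0.1 * y_sd, d_med, y_sd)
  starts <- list(pmin(pmax(log(init), lower), upper))
  extra <- with_seed(seed, {
    lapply(seq_len(max(0L, restarts - 1L)), function(i)
      runif(3, lower, upper))
  })
  starts <- c(starts, extra)

  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      optim(s0, gpr_nll, inputs = inputs, targets_centered = yc,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("hyperparameter optimization failed", call. = FALSE)
  sigma <- exp(best$par[1]); l <- exp(best$par[2]); s_rbf <- exp(best$par[3])

  Kmat <- rbf_kernel(inputs, inputs, l, s_rbf) + diag(sigma^2, p)
  L <- gpr_chol(Kmat)
  alpha <- backsolve(t(L), forwardsolve(L, yc))
  structure(
    list(inputs = inputs, targets = targets, target_means = mu_v,
         sigma = sigma, l = l, sigma_rbf = s_rbf,
         L = L, alpha = alpha, nll = best$value),
    class = "gpr_model")
}

#' Construct a GP model at fixed hyperparameters
#'
#' Skips marginal-likelihood optimization; useful when \eqn{\xi} is known
#' or for controlled experiments.
#'
#' @inheritParams fit_gpr
#' @param sigma,l,sigma_rbf noise scale (`>= 0`), length-scale (`> 0`) and
#'   signal scale (`> 0`).
#' @return A `gpr_model` (see [fit_gpr()]).
#' @export
gpr_model <- function(inputs, targets, sigma, l, sigma_rbf) {
  inputs <- as.matrix(inputs)
  targets <- as.matrix(targets)
  if (sigma < 0 || l <= 0 || sigma_rbf <= 0)
    stop("hyperparameters must be positive (sigma may be zero)", call. = FALSE)
  p <- nrow(inputs)
  mu_v <- colMeans(targets)
  yc <- sweep(targets, 2L, mu_v)
  Kmat <- rbf_kernel(inputs, inputs, l, sigma_rbf) + diag(sigma^2, p)
  L <- gpr_chol(Kmat)
  alpha <- backsolve(t(L), forwardsolve(L, yc))
  structure(
    list(inputs = inputs, targets = targets, target_means = mu_v,
         sigma = sigma, l = l, sigma_rbf = sigma_rbf,
         L = L, alpha = alpha, nll = NA_real_),
    class = "gpr_model")
}

#' GP posterior at query points
#'
#' Posterior mean
#' \eqn{\mu^* = \mu_V + K(q, X)(K(X,X) + \sigma^2 I)^{-1}(V - \mu_V)} and the
#' diagonal of the predictive covariance
#' \eqn{K(q,q) + \sigma^2 I - K(q,X)(K(X,X)+\sigma^2 I)^{-1}K(X,q)}.
#'
#' @param object a fitted `gpr_model`.
#' @param query numeric matrix of query points, `d` columns matching training.
#' @param ... unused.
#' @return A list with `mean` (q-by-n_out matrix) and `variance` (length-q
#'   vector, shared across outputs since the kernel is shared).
#' @export
predict.gpr_model <- function(object, query, ...) {
  query <- as.matrix(query)
  if (ncol(query) != ncol(object$inputs))
    stop(sprintf("query has %d columns but training inputs have %d",
                 ncol(query), ncol(object$inputs)), call. = FALSE)
  Ks <- rbf_kernel(query, object$inputs, object$l, object$sigma_rbf)
  mean <- sweep(Ks %*% object$alpha, 2L, object$target_means, "+")
  W <- forwardsolve(object$L, t(Ks))
  variance <- pmax(object$sigma_rbf^2 + object$sigma^2 - colSums(W^2), 0)
  list(mean = mean, variance = variance)
}

#' Smooth RNA velocity onto cell populations
#'
#' Predicts one velocity vector per cell population by GP regression of
#' cell velocities on cell expression, evaluated at the population
#' centroids. In `"per-cluster"` mode (default) one GP is fitted per
#' mixture cluster on that cluster's cells; `"global"` mode fits a single
#' GP on all cells, subsampled to at most `max_train` points. Clusters with
#' fewer than 2 cells fall back to the mean member velocity.
#'
#' @param ds an [expression_dataset()] (expression from the spliced layer,
#'   targets from the velocity layer).
#' @param pops a `cell_populations` tibble from [refine_clusters()].
#' @param mode `"per-cluster"` or `"global"`.
#' @param restarts,seed,max_train optimizer restarts, seed, and the
#'   subsampling cap for global mode.
#' @param verbose emit progress messages.
#' @return `pops` with the `velocity` list-column filled (one numeric
#'   vector per CP).
#' @export
smooth_population_velocities <- function(ds, pops, mode = c("per-cluster", "global"),
                                         restarts = 3L, seed = 1L,
                                         max_train = 1000L, verbose = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"))
  mode <- match.arg(mode)
  x <- ds$spliced
  v <- ds$velocity

  if (mode == "global") {
    idx <- seq_len(nrow(x))
    if (length(idx) > max_train) {
      idx <- with_seed(derive_seed(seed, 99), sort(sample(idx, max_train)))
    }
    model <- fit_gpr(x[idx, , drop = FALSE], v[idx, , drop = FALSE],
                     restarts = restarts, seed = seed)
    mu <- predict(model, centroid_matrix(pops))$mean
    pops$velocity <- lapply(seq_len(nrow(pops)), function(i) mu[i, ])
    return(pops)
  }

  for (k in unique(pops$parent_cluster)) {
    rows <- which(pops$parent_cluster == k)
    cells <- sort(unlist(pops$members[rows]))
    cent <- do.call(rbind, pops$centroid[rows])
    if (length(cells) < 2) {
      pt_log(verbose, "cluster %d has < 2 cells; using mean member velocity", k)
      vbar <- colMeans(v[cells, , drop = FALSE])
      pops$velocity[rows] <- rep(list(vbar), length(rows))
      next
    }
    model <- fit_gpr(x[cells, , drop = FALSE], v[cells, , drop = FALSE],
                     restarts = restarts, seed = derive_seed(seed, k))
    mu <- predict(model, cent)$mean
    pops$velocity[rows] <- lapply(seq_along(rows), function(j) mu[j, ])
    pt_log(verbose, "cluster %d: GP fitted on %d cells, %d populations",
           k, length(cells), length(rows))
  }
  pops
}
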