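#' Gaussian mixture clustering of cells by expectation-maximization
#'
#' Cells are modelled as draws from a K-component Gaussian mixture with
#' diagonal covariance, fitted directly in the (optionally gene-restricted)
#' expression space rather than a reduced embedding. The E-step computes
#' posterior responsibilities in log space; the M-step updates weights,
#' means and per-gene variances from responsibility-weighted moments.
#'
#' @name gmm
NULL

GMM_VAR_FLOOR <- 1e-6

#' Log-density of a diagonal-covariance Gaussian
#'
#' Evaluates \eqn{\log N(x \mid \mu, \mathrm{diag}(\sigma^2))} in log space,
#' so densities remain finite in high dimension.
#'
#' @param x numeric vector (one cell's expression profile).
#' @param mu numeric vector of component means, same length as `x`.
#' @param sigma2 numeric vector of per-gene variances, all `> 0`.
#' @return The log-density, a single finite number.
#' @export
gmm_log_density <- function(x, mu, sigma2) {
  if (any(sigma2 <= 0)) stop("all variances must be strictly positive", call. = FALSE)
  -0.5 * sum(log(2 * pi * sigma2) + (x - mu)^2 / sigma2)
}

# m x K matrix of per-component log densities, vectorized over cells
component_log_densities <- function(x, mu, sigma2) {
  m <- nrow(x); K <- nrow(mu)
  out <- matrix(0, m, K)
  for (k in seq_len(K)) {
    out[, k] <- -0.5 * (sum(log(2 * pi * sigma2[k, ])) +
                          rowSums(sweep(x, 2L, mu[k, ])^2 / rep(sigma2[k, ], each = m)))
  }
  out
}

#' E-step: posterior responsibilities
#'
#' Computes \eqn{\gamma_{ir} \propto \omega_r N(x_i \mid \mu_r, \sigma^2_r)}
#' with rows normalized to one, via the log-sum-exp trick.
#'
#' @param x cells-by-genes numeric matrix.
#' @param model a `mixture_model` (see [fit_gmm()]) or any list carrying
#'   `weights`, `means`, `variances`.
#' @return An m-by-K responsibility matrix whose rows sum to 1.
#' @export
gmm_e_step <- function(x, model) {
  x <- as.matrix(x)
  logd <- component_log_densities(x, model$means, model$variances)
  logpost <- sweep(logd, 2L, log(model$weights), "+")
  norm <- logsumexp_rows(logpost)
  if (any(!is.finite(norm))) {
    bad <- which(!is.finite(norm))[1]
    stop(sprintf("all mixture components underflow for cell %d", bad), call. = FALSE)
  }
  gamma <- exp(logpost - norm)
  gamma / rowSums(gamma)
}

#' M-step: weighted parameter updates
#'
#' Updates mixture weights as mean responsibilities, means as
#' responsibility-weighted cell averages, and per-gene variances as
#' responsibility-weighted squared deviations about the new means, floored
#' at the variance floor. A component whose total responsibility collapses
#' (below `1e-12`) is re-seeded at the cell currently worst explained by the
#' model (lowest maximum responsibility), keeping K fixed.
#'
#' @param x cells-by-genes numeric matrix.
#' @param gamma m-by-K responsibility matrix with unit row sums.
#' @return A list with `weights`, `means`, `variances`.
#' @export
gmm_m_step <- function(x, gamma) {
  x <- as.matrix(x)
  m <- nrow(x); K <- ncol(gamma)
  nk <- colSums(gamma)
  collapsed <- which(nk < 1e-12)
  if (length(collapsed) > 0) {
    worst <- order(apply(gamma, 1L, max))
    for (j in seq_along(collapsed)) {
      i <- worst[j]
      gamma[i, ] <- 0
      gamma[i, collapsed[j]] <- 1
    }
    nk <- colSums(gamma)
  }
  weights <- nk / m
  means <- crossprod(gamma, x) / nk
  variances <- matrix(0, K, ncol(x))
  for (k in seq_len(K)) {
    dev2 <- sweep(x, 2L, means[k, ])^2
    variances[k, ] <- colSums(gamma[, k] * dev2) / nk[k]
  }
  variances <- variances + GMM_VAR_FLOOR
  list(weights = weights, means = means, variances = variances)
}

# total log-likelihood of the mixture (Eq. of the observed-data likelihood)
gmm_log_likelihood <- function(x, model) {
  logd <- component_log_densities(as.matrix(x), model$means, model$variances)
  sum(logsumexp_rows(sweep(logd, 2L, log(model$weights), "+")))
}

# k-means++ center selection (seeded by the caller's RNG state)
kmeanspp_centers <- function(x, K) {
  m <- nrow(x)
  centers <- integer(K)
  centers[1] <- sample.int(m, 1L)
  if (K > 1) {
    d2 <- rowSums(sweep(x, 2L, x[centers[1], ])^2)
    for (k in 2:K) {
      if (sum(d2) <= 0) {
        centers[k] <- sample.int(m, 1L)
      } else {
        centers[k] <- sample.int(m, 1L, prob = d2 / sum(d2))
      }
      d2 <- pmin(d2, rowSums(sweep(x, 2L, x[centers[k], ])^2))
    }
  }
  x[centers, , drop = FALSE]
}

#' Fit a Gaussian mixture model to cells
#'
#' Runs EM from a seeded k-means++ initialization until the relative change
#' in total log-likelihood drops below `tol` or `max_iter` is reached.
#' Initial variances are the global per-gene variances and initial weights
#' uniform. `covariance = "spherical"` ties the per-gene variances of each
#' component to their mean.
#'
#' @param x cells-by-genes numeric matrix, or an [expression_dataset()]
#'   (its spliced layer is used).
#' @param K number of mixture components, `1 <= K <=` number of cells.
#' @param seed integer seed for the initialization.
#' @param tol relative log-likelihood convergence tolerance (default `1e-6`).
#' @param max_iter maximum EM iterations (default 300).
#' @param covariance `"diagonal"` (default) or `"spherical"`.
#' @return A `mixture_model` object: list with `K`, `weights`, `means`,
#'   `variances`, `responsibilities`, `assignments` (per-cell argmax
#'   component), `log_likelihood_trace`, `converged`, `n_iter`.
#' @export
fit_gmm <- function(x, K, seed = 1L, tol = 1e-6, max_iter = 300L,
                    covariance = c("diagonal", "spherical")) {
  covariance <- match.arg(covariance)
  if (inherits(x, "expression_dataset")) x <- x$spliced
  x <- as.matrix(x)
  m <- nrow(x)
  if (K < 1 || K > m) stop(sprintf("K = %d outside [1, %d]", K, m), call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) stop("data contain non-finite values", call. = FALSE)

  model <- with_seed(seed, {
    means <- kmeanspp_centers(x, K)
    gvar <- apply(x, 2L, var)
    gvar[!is.finite(gvar) | gvar <= 0] <- 1
    list(weights = rep(1 / K, K),
         means = means,
         variances = matrix(gvar + GMM_VAR_FLOOR, K, ncol(x), byrow = TRUE))
  })

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  gamma <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    gamma <- gmm_e_step(x, model)
    model[c("weights", "means", "variances")] <- gmm_m_step(x, gamma)
    if (covariance == "spherical") {
      model$variances[] <- rowMeans(model$variances)
    }
    ll <- gmm_log_likelihood(x, model)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  gamma <- gmm_e_step(x, model)
  structure(
    list(K = K, weights = model$weights, means = model$means,
         variances = model$variances, responsibilities = gamma,
         assignments = max.col(gamma, ties.method = "first"),
         log_likelihood_trace = trace, converged = converged, n_iter = iter,
         covariance = covariance, n_cells = m, n_genes = ncol(x)),
    class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("<mixture_model> K = %d components, %d cells x %d genes (%s covariance)\n",
              x$K, x$n_cells, x$n_genes, x$covariance))
  cat(sprintf("  log-likelihood %.4f after %d iterations (%sconverged)\n",
              utils::tail(x$log_likelihood_trace, 1), x$n_iter,
              if (x$converged) "" else "not "))
  invisible(x)
}

#' Choose the number of mixture components by BIC
#'
#' Fits the mixture for each candidate K and returns the K minimizing
#' \eqn{\mathrm{BIC} = -2\,\ell + p\,\log m} with
#' \eqn{p = K - 1 + 2Kn} free parameters (weights, means, variances).
#'
#' @param x cells-by-genes matrix or [expression_dataset()].
#' @param K_range integer vector of candidate component counts.
#' @param seed integer seed shared across fits.
#' @param ... passed through to [fit_gmm()].
#' @return A list with `K` (the selection), `bic` (a tibble of `K`,
#'   `log_likelihood`, `bic`), and `models` (the fitted candidates).
#' @export
select_K <- function(x, K_range = 2:8, seed = 1L, ...) {
  if (length(K_range) == 0) stop("K_range is empty", call. = FALSE)
  if (inherits(x, "expression_dataset")) x <- x$spliced
  m <- nrow(x); n <- ncol(x)
  if (any(K_range < 1 | K_range > m))
    stop(sprintf("K_range must lie within [1, %d]", m), call. = FALSE)
  fits <- lapply(K_range, function(K) fit_gmm(x, K, seed = seed, ...))
  ll <- vapply(fits, function(f) utils::tail(f$log_likelihood_trace, 1), numeric(1))
  p <- K_range - 1 + 2 * K_range * n
  bic <- -2 * ll + p * log(m)
  best <- which.min(bic)
  list(K = K_range[best],
       bic = tibble::tibble(K = K_range, log_likelihood = ll, bic = bic),
       models = setNames(fits, paste0("K", K_range)))
}
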