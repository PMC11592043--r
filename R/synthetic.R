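#' Seeded synthetic branching single-cell datasets
#'
#' Generates desk-scale datasets that mimic the structure a branching
#' dynamic-process simulator produces: per-cell ground-truth time and
#' branch label, smooth branch-specific expression programs, analytic RNA
#' velocities, and spliced/unspliced layers tied by the steady-state
#' kinetic relation \eqn{v = \beta u - \gamma s}. Four topologies are
#' available: `linear` (one branch), `bifurcating` (trunk plus two
#' branches), `trifurcating` (trunk plus three), and `cycletree` (a cycle
#' with four tree branches rooted on it, so every path starts on the
#' cycle).
#'
#' Gene programs are sums of 2-4 logistic (sigmoid) terms with random
#' centers, widths and directions; branch-specific terms switch on only
#' after the branch point, so programs are continuous across branch points.
#' Cycle programs use smooth periodic bumps, so expression at cycle phase 0
#' equals phase 1 exactly. Velocity is the analytic time derivative of the
#' program. Gaussian noise is added to spliced and velocity layers at
#' `noise_sd` times each gene's signal standard deviation; the unspliced
#' layer is derived by inverting the kinetic relation and clipping at zero.
#'
#' @name synthetic
NULL

#' Specify a synthetic topology
#'
#' @param kind one of `"linear"`, `"bifurcating"`, `"trifurcating"`,
#'   `"cycletree"`.
#' @param n_cells number of cells, at least 50 (default 500).
#' @param n_genes number of genes, at least 10 (default 50).
#' @param noise_sd Gaussian noise level as a fraction of each gene's signal
#'   standard deviation (default 0.05).
#' @param seed integer seed; identical specs generate bit-identical data.
#' @return A `topology_spec` list.
#' @export
topology_spec <- function(kind = c("linear", "bifurcating", "trifurcating", "cycletree"),
                          n_cells = 500L, n_genes = 50L, noise_sd = 0.05,
                          seed = 1L) {
  kind <- match.arg(kind)
  if (n_cells < 50) stop("n_cells must be >= 50", call. = FALSE)
  if (n_genes < 10) stop("n_genes must be >= 10", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(kind = kind, n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "topology_spec")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# branch layout per topology: trunk interval plus terminal branches
topology_layout <- function(kind) {
  switch(kind,
    linear = list(t_split = NA, lineages = list(branch1 = NULL)),
    bifurcating = list(t_split = 0.5,
                       lineages = list(branch1 = NULL, branch2 = NULL)),
    trifurcating = list(t_split = 0.4,
                        lineages = list(branch1 = NULL, branch2 = NULL,
                                        branch3 = NULL)),
    cycletree = list(t_split = 0.25,
                     lineages = list(branch1 = NULL, branch2 = NULL,
                                     branch3 = NULL, branch4 = NULL)))
}

# per-gene shared (trunk) program: value and analytic time derivative
draw_base_programs <- function(n_genes) {
  lapply(seq_len(n_genes), function(g) {
    nb <- sample(2:4, 1)
    list(a = runif(nb, 0.3, 1.5),
         c = runif(nb, 0, 1),
         w = runif(nb, 0.05, 0.15),
         dir = sample(c(-1, 1), nb, replace = TRUE))
  })
}

# vectorized over a time vector t
base_value <- function(prog, t) {
  out <- rep(0.2, length(t))
  for (j in seq_along(prog$a)) {
    out <- out + prog$a[j] * sigmoid(prog$dir[j] * (t - prog$c[j]) / prog$w[j])
  }
  out
}
base_deriv <- function(prog, t) {
  out <- numeric(length(t))
  for (j in seq_along(prog$a)) {
    s <- sigmoid(prog$dir[j] * (t - prog$c[j]) / prog$w[j])
    out <- out + prog$a[j] * prog$dir[j] / prog$w[j] * s * (1 - s)
  }
  out
}

# branch-specific additions: sigmoids centered well past the branch point,
# so the program is continuous there
draw_branch_deltas <- function(n_genes, t_start, p_active = 0.5) {
  lapply(seq_len(n_genes), function(g) {
    if (runif(1) > p_active) return(NULL)
    nb <- sample(1:2, 1)
    w <- runif(nb, 0.02, 0.05)
    # centers at least six widths past the branch point: the sigmoid is
    # below exp(-6) of its amplitude there, keeping programs continuous
    list(a = runif(nb, 0.5, 2),
         c = t_start + 6 * w + runif(nb, 0, 1 - t_start),
         w = w)
  })
}

delta_value <- function(d, t) {
  out <- numeric(length(t))
  if (is.null(d)) return(out)
  for (j in seq_along(d$a)) {
    out <- out + d$a[j] * sigmoid((t - d$c[j]) / d$w[j])
  }
  out
}
delta_deriv <- function(d, t) {
  out <- numeric(length(t))
  if (is.null(d)) return(out)
  for (j in seq_along(d$a)) {
    s <- sigmoid((t - d$c[j]) / d$w[j])
    out <- out + d$a[j] / d$w[j] * s * (1 - s)
  }
  out
}

# periodic cycle programs: smooth bumps in the cycle phase, exactly
# periodic with period 1
draw_cycle_programs <- function(n_genes) {
  lapply(seq_len(n_genes), function(g) {
    nb <- sample(2:4, 1)
    list(a = runif(nb, 0.3, 1.5),
         kappa = runif(nb, 2, 10),
         phi = runif(nb, 0, 1))
  })
}

cycle_value <- function(prog, phase) {
  out <- rep(0.2, length(phase))
  for (j in seq_along(prog$a)) {
    out <- out + prog$a[j] *
      exp(prog$kappa[j] * (cos(2 * pi * (phase - prog$phi[j])) - 1))
  }
  out
}
# derivative with respect to global time t = phase * t_cycle
cycle_deriv <- function(prog, phase, t_cycle) {
  out <- numeric(length(phase))
  for (j in seq_along(prog$a)) {
    out <- out + prog$a[j] *
      exp(prog$kappa[j] * (cos(2 * pi * (phase - prog$phi[j])) - 1)) *
      prog$kappa[j] * (-sin(2 * pi * (phase - prog$phi[j]))) * 2 * pi
  }
  out / t_cycle
}

#' Generate a synthetic dataset from a topology spec
#'
#' @param spec a [topology_spec()].
#' @return An [expression_dataset()] with `truth_time` and `truth_branch`
#'   filled. Cells on shared segments (trunk or cycle) are labelled
#'   `"trunk"` / `"cycle"`; terminal segments are `"branch1"`, `"branch2"`,
#'   etc.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "topology_spec"))
  with_seed(spec$seed, generate_dataset_impl(spec))
}

generate_dataset_impl <- function(spec) {
  m <- spec$n_cells; n <- spec$n_genes
  layout <- topology_layout(spec$kind)
  lineage_names <- names(layout$lineages)
  t_split <- layout$t_split
  cyclic <- spec$kind == "cycletree"

  # ground truth: lineage uniformly, time uniform along the lineage
  lineage <- sample(lineage_names, m, replace = TRUE)
  tt <- runif(m)
  branch <- lineage
  if (!is.na(t_split)) {
    branch[tt < t_split] <- if (cyclic) "cycle" else "trunk"
  }

  base <- draw_base_programs(n)
  cycle <- if (cyclic) draw_cycle_programs(n) else NULL
  deltas <- NULL
  if (length(lineage_names) > 1 || cyclic) {
    deltas <- lapply(lineage_names, function(b)
      draw_branch_deltas(n, t_start = t_split,
                         p_active = if (cyclic) 0.7 else 0.5))
    names(deltas) <- lineage_names
  }

  mu <- matrix(0, m, n)
  vel <- matrix(0, m, n)
  t_cycle <- if (cyclic) t_split else NA
  if (cyclic) {
    on_cycle <- tt < t_cycle
    phase <- tt / t_cycle
    for (g in seq_len(n)) {
      mu[on_cycle, g] <- cycle_value(cycle[[g]], phase[on_cycle])
      vel[on_cycle, g] <- cycle_deriv(cycle[[g]], phase[on_cycle], t_cycle)
      root <- cycle_value(cycle[[g]], 0)
      for (li in lineage_names) {
        sel <- !on_cycle & lineage == li
        if (!any(sel)) next
        mu[sel, g] <- root + delta_value(deltas[[li]][[g]], tt[sel])
        vel[sel, g] <- delta_deriv(deltas[[li]][[g]], tt[sel])
      }
    }
  } else {
    for (g in seq_len(n)) {
      mu[, g] <- base_value(base[[g]], tt)
      vel[, g] <- base_deriv(base[[g]], tt)
      if (!is.null(deltas)) {
        for (li in lineage_names) {
          sel <- lineage == li & tt >= t_split
          if (!any(sel)) next
          mu[sel, g] <- mu[sel, g] + delta_value(deltas[[li]][[g]], tt[sel])
          vel[sel, g] <- vel[sel, g] + delta_deriv(deltas[[li]][[g]], tt[sel])
        }
      }
    }
  }

  sd_mu <- apply(mu, 2L, sd)
  sd_v <- apply(vel, 2L, sd)
  spliced <- mu + matrix(rnorm(m * n), m, n) *
    rep(spec$noise_sd * sd_mu, each = m)
  velocity <- vel + matrix(rnorm(m * n), m, n) *
    rep(spec$noise_sd * sd_v, each = m)

  # kinetic rates; unspliced inverts v = beta*u - gamma*s, clipped at zero
  beta_g <- runif(n, 0.5, 2)
  gamma_g <- runif(n, 0.2, 1)
  unspliced <- sweep(velocity + sweep(spliced, 2L, gamma_g, "*"),
                     2L, beta_g, "/")
  unspliced <- pmax(unspliced, 0)

  ds <- expression_dataset(
    spliced, unspliced, velocity,
    cell_ids = sprintf("cell_%04d", seq_len(m)),
    gene_ids = sprintf("gene_%03d", seq_len(n)),
    truth_time = tt, truth_branch = branch)
  attr(ds, "kinetics") <- list(beta = beta_g, gamma = gamma_g)
  attr(ds, "spec") <- spec
  ds
}
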