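#' Log10-spaced hyperparameter grid
#'
#' Grids of candidate hyperparameter values are log10-spaced between stated
#' endpoints; hyperparameter inference is exact Gibbs sampling over the grid.
#'
#' @param lo,hi positive endpoints, `lo < hi`; both included.
#' @param n number of points, at least 2.
#' @param spacing only `"log10"` is supported.
#' @return ascending numeric vector of length `n`.
#' @export
#' @examples
#' make_grid(1, 80, 40)   # retina-scale grid, micrometres
#' make_grid(0.2, 2, 20)  # normalized body-axis grid
make_grid <- function(lo, hi, n, spacing = "log10") {
  spacing <- match.arg(spacing)
  if (lo <= 0) stop("grid endpoints must be positive")
  if (hi <= lo) stop("need lo < hi")
  if (n < 2) stop("need at least 2 grid points")
  10^seq(log10(lo), log10(hi), length.out = n)
}

#' Hyperparameter specification for one relation
#'
#' Builds the gridded hyperprior of an observation model. Defaults follow
#' the grids used for the three connectome datasets the model was designed
#' around: logistic-Bernoulli contact graphs (40 log10-spaced points in
#' `[1, 80]` micrometres for both the exponential-prior means, ceiling
#' candidates `{0.95, 0.9, 0.7}`), logistic-Poisson synapse-count graphs
#' (20 points in `[0.2, 2]` for the threshold prior mean and the global
#' logistic scale, 20 points in `[2, 20]` for the rate-scale prior mean,
#' `rate_min = 0.01`), and the per-component-ceiling Bernoulli variant
#' (50 points in `[10, 500]` with the global scale tied to `mu_hp / 10`,
#' floor candidates `{0.001, 0.01, 0.02}`, Beta shape candidates
#' `{0.1, 1, 2}`).
#'
#' @param kind one of `"bernoulli"`, `"poisson"`, `"bernoulli_pp"`.
#' @param ... named grid overrides, see Details.
#' @param eta_fixed optional list pinning component parameters to fixed
#'   values (e.g. `list(mu = 5, lambda = 1)`); used for validation runs
#'   where the partition posterior must be enumerable exactly. When set,
#'   prior draws return these values and the parameter log-prior is 0.
#' @return an object of class `ddsbm_hyperspec`.
#' @export
hyper_spec <- function(kind = c("bernoulli", "poisson", "bernoulli_pp"), ...,
                       eta_fixed = NULL) {
  kind <- match.arg(kind)
  dots <- list(...)
  grids <- switch(kind,
    bernoulli = list(mu_hp = make_grid(1, 80, 40),
                     lambda_hp = make_grid(1, 80, 40),
                     pmax = c(0.95, 0.9, 0.7),
                     pmin = c(0.001, 0.01, 0.02)),
    poisson = list(mu_hp = make_grid(0.2, 2, 20),
                   lambda = make_grid(0.2, 2, 20),
                   ratescale_hp = make_grid(2, 20, 20)),
    bernoulli_pp = list(mu_hp = make_grid(10, 500, 50),
                        pmin = c(0.001, 0.01, 0.02),
                        alpha_hp = c(0.1, 1.0, 2.0),
                        beta_hp = c(0.1, 1.0, 2.0)))
  for (nm in names(dots)) {
    if (!nm %in% names(grids)) stop("unknown grid: ", nm)
    if (length(dots[[nm]]) < 1) stop("empty grid: ", nm)
    grids[[nm]] <- dots[[nm]]
  }
  for (nm in names(grids)) {
    ok <- if (nm == "pmin") all(grids[[nm]] >= 0) else all(grids[[nm]] > 0)
    if (!ok) stop("grid values for ", nm, " out of range")
  }
  if (kind != "poisson" && "pmin" %in% names(grids) && "pmax" %in% names(grids) &&
      max(grids$pmin) >= min(grids$pmax))
    stop("every pmin candidate must lie below every pmax candidate")
  extra <- if (kind == "poisson") list(rate_min = 0.01) else list()
  structure(c(list(kind = kind, grids = grids, eta_fixed = eta_fixed), extra),
            class = "ddsbm_hyperspec")
}

grid_sizes <- function(spec) lengths(spec$grids)

# Current hyperparameter values given grid indices (named integer vector).
hyper_values <- function(spec, idx) {
  vals <- mapply(function(g, i) g[[i]], spec$grids, idx, SIMPLIFY = FALSE)
  if (spec$kind == "bernoulli_pp") vals$lambda <- vals$mu_hp / 10
  if (spec$kind == "poisson") vals$rate_min <- spec$rate_min
  vals
}

# theta vector handed to the C++ pair-likelihood kernels.
theta_vec <- function(spec, vals) {
  switch(spec$kind,
         bernoulli = c(vals$pmax, vals$pmin),
         poisson = c(vals$lambda, vals$rate_min),
         bernoulli_pp = c(vals$lambda, vals$pmin))
}

#' Chinese restaurant process partition log-probability
#'
#' The CRP prior over assignments: `P(c) = alpha^K * prod_k (N_k - 1)! /
#' prod_{n=0}^{N-1} (alpha + n)`, where K is the number of occupied types
#' and `N_k` their sizes. Larger `alpha` favours more types.
#'
#' @param labels integer type assignment vector.
#' @param alpha concentration parameter, positive.
#' @return log-probability of the partition.
#' @export
crp_log_prior <- function(labels, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  n <- length(labels)
  sizes <- tabulate(labels)
  sizes <- sizes[sizes > 0]
  length(sizes) * log(alpha) + sum(lgamma(sizes)) +
    lgamma(alpha) - lgamma(alpha + n)
}

#' CRP conditional assignment weights
#'
#' Unnormalized Gibbs weights for one entity given the others: weight
#' `m_k` for each existing type of size `m_k`, and `alpha` for a new type.
#'
#' @param counts_minus_i per-type sizes with the entity removed.
#' @param alpha concentration parameter.
#' @return numeric vector `c(counts_minus_i, alpha)`; normalizing it gives
#'   the conditional probabilities (existing types first, new type last).
#' @export
crp_conditional <- function(counts_minus_i, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  if (any(counts_minus_i < 0)) stop("counts must be nonnegative")
  c(counts_minus_i, alpha)
}

#' Log-probability of the gridded hyperparameters
#'
#' The hyperprior is uniform over the Cartesian product of all grids:
#' `-log(prod(grid sizes))` for any index combination.
#'
#' @param spec a `ddsbm_hyperspec`.
#' @return scalar log-probability.
#' @export
grid_log_prior <- function(spec) {
  sizes <- grid_sizes(spec)
  if (any(sizes == 0)) stop("empty grid")
  -sum(log(sizes))
}

# All set partitions of 1..n as a list of label vectors (canonical order).
# Enumeration oracle used by validation tests; grows as the Bell numbers,
# so keep n small.
enumerate_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in enumerate_partitions(n - 1)) {
    k <- max(p)
    for (j in seq_len(k + 1)) out[[length(out) + 1L]] <- c(p, j)
  }
  out
}
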