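PROB_FLOOR <- 1e-12

clamp_prob <- function(p) pmin(pmax(p, PROB_FLOOR), 1 - PROB_FLOOR)

#' Logistic-distance Bernoulli connection probability
#'
#' The probability that two entities of types m and n at distance `d`
#' connect: `p* = 1 / (1 + exp((d - mu) / lambda))`, rescaled to
#' `p = p* (p_max - p_min) + p_min`. Strictly decreasing in `d`; the
#' ceiling `p_max` and floor `p_min` are global per-graph parameters (the
#' floor absorbs reconstruction errors: even far-apart cells have a small
#' base connection rate).
#'
#' @param d nonnegative distance(s).
#' @param mu component threshold (distance at which the unscaled
#'   probability is 1/2), positive.
#' @param lambda component length scale, positive.
#' @param p_max,p_min global ceiling and floor, `0 <= p_min < p_max <= 1`.
#' @return probability in `(p_min, p_max)`, vectorized over `d`.
#' @export
logistic_bernoulli_prob <- function(d, mu, lambda, p_max = 1, p_min = 0) {
  if (any(lambda <= 0)) stop("lambda must be positive")
  if (any(p_min < 0) || any(p_max > 1) || any(p_min >= p_max))
    stop("need 0 <= p_min < p_max <= 1")
  pstar <- 1 / (1 + exp((d - mu) / lambda))
  pstar * (p_max - p_min) + p_min
}

#' Logistic-distance Bernoulli log-likelihood
#'
#' @inheritParams logistic_bernoulli_prob
#' @param obs observation(s) in `{0, 1}`.
#' @return log-probability of `obs`; finite for any valid parameters
#'   (probabilities are clamped away from 0 and 1 before the log).
#' @export
logistic_bernoulli_loglik <- function(obs, d, mu, lambda, p_max = 1, p_min = 0) {
  if (!all(obs %in% c(0, 1))) stop("bernoulli observations must be 0 or 1")
  p <- clamp_prob(logistic_bernoulli_prob(d, mu, lambda, p_max, p_min))
  ifelse(obs == 1, log(p), log1p(-p))
}

#' Log-prior of logistic-Bernoulli component parameters
#'
#' Exponential priors on the threshold and length scale, parameterized by
#' their means so that the hyperparameter grids live on the same scale as
#' the data's distances: `mu ~ Exp(mean = mu_hp)`,
#' `lambda ~ Exp(mean = lambda_hp)`.
#'
#' @param mu,lambda component parameters, positive.
#' @param mu_hp,lambda_hp prior means, positive.
#' @return summed log-density, vectorized.
#' @export
eta_log_prior_logistic <- function(mu, lambda, mu_hp, lambda_hp) {
  if (any(c(mu, lambda, mu_hp, lambda_hp) < 0)) stop("parameters must be nonnegative")
  stats::dexp(mu, rate = 1 / mu_hp, log = TRUE) +
    stats::dexp(lambda, rate = 1 / lambda_hp, log = TRUE)
}

#' Logistic-distance Poisson synapse-count rate
#'
#' Expected synapse count between two entities at distance `d`: the
#' logistic `1 / (1 + exp((d - mu) / lambda))` rescaled to lie between
#' `r_min` and the component ceiling. So a component with `mu = 5` and
#' `r_mn = 20` gives on average 20 synapses for pairs much closer than 5
#' and `r_min` for far pairs. `lambda` and `r_min` are global per-graph
#' parameters; `mu` and `r_mn` are learned per component.
#'
#' @param d nonnegative distance(s).
#' @param mu component threshold, positive.
#' @param r component rate scale, must exceed `r_min`.
#' @param lambda global logistic length scale, positive.
#' @param r_min global floor rate, nonnegative.
#' @return rate in `(r_min, r)`, vectorized over `d`.
#' @export
logistic_poisson_rate <- function(d, mu, r, lambda, r_min = 0.01) {
  if (any(lambda <= 0)) stop("lambda must be positive")
  if (any(r <= r_min)) stop("rate scale must exceed r_min")
  rstar <- 1 / (1 + exp((d - mu) / lambda))
  rstar * (r - r_min) + r_min
}

#' Logistic-distance Poisson log-likelihood
#'
#' @inheritParams logistic_poisson_rate
#' @param count nonnegative integer observation(s).
#' @return Poisson log-pmf at the distance-dependent rate.
#' @export
logistic_poisson_loglik <- function(count, d, mu, r, lambda, r_min = 0.01) {
  if (any(count < 0) || any(count != round(count)))
    stop("counts must be nonnegative integers")
  stats::dpois(count, pmax(logistic_poisson_rate(d, mu, r, lambda, r_min), 1e-10),
               log = TRUE)
}

#' Per-component-ceiling Bernoulli connection probability
#'
#' Reparameterized logistic-distance Bernoulli in which the ceiling of the
#' logistic is a per-component parameter `p` with a global Beta prior,
#' while the length scale `lambda` is a global per-graph parameter (tied
#' to the threshold hyperprior as `mu_hp / 10` in the default spec).
#'
#' @param d nonnegative distance(s).
#' @param mu component threshold, positive.
#' @param p component ceiling in `(p_min, 1)`.
#' @param lambda global length scale, positive.
#' @param p_min global floor.
#' @return probability in `(p_min, p)`, vectorized over `d`.
#' @export
percomp_pmax_bernoulli_prob <- function(d, mu, p, lambda, p_min = 0.001) {
  if (any(p <= 0) || any(p >= 1)) stop("p must lie in (0,1)")
  if (any(lambda <= 0)) stop("lambda must be positive")
  pstar <- 1 / (1 + exp((d - mu) / lambda))
  pstar * (p - p_min) + p_min
}

#' Log-prior of the per-component ceiling
#'
#' The ceiling is drawn as `p = p_min + (1 - p_min) u` with
#' `u ~ Beta(alpha_hp, beta_hp)`, so the prior support never crosses the
#' floor; the density includes the change-of-variables constant.
#'
#' @param p ceiling value(s) in `(p_min, 1)`.
#' @param alpha_hp,beta_hp Beta shape hyperparameters.
#' @param p_min global floor.
#' @return log-density, vectorized.
#' @export
percomp_pmax_log_prior <- function(p, alpha_hp, beta_hp, p_min = 0.001) {
  u <- (p - p_min) / (1 - p_min)
  # keep the density finite at the support edges (Beta with shape < 1 diverges)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  stats::dbeta(u, alpha_hp, beta_hp, log = TRUE) - log(1 - p_min)
}

#' Collapsed soma-depth log marginal likelihood
#'
#' Each type has a typical depth: depths of its members are
#' `N(mu_k, sigma2_k)` with a conjugate Normal/scaled-inverse-chi-squared
#' prior `mu_k ~ N(mu0, sigma2_k / kappa0)`,
#' `sigma2_k ~ Inv-chi2(nu0, sigma02)`. The per-type mean and variance are
#' integrated out; the marginal is computed as a sequential product of
#' Student-t posterior predictives and is therefore exchangeable in the
#' data order.
#'
#' @param x numeric vector of depths of one type's members (normalized
#'   depth units); `NA`s are dropped.
#' @param hyper numeric vector `c(mu0, kappa0, sigma02, nu0)`.
#' @return log marginal likelihood; 0 for an empty vector.
#' @export
soma_depth_loglik <- function(x, hyper = c(mu0 = 0.5, kappa0 = 1,
                                           sigma02 = 0.04, nu0 = 2)) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(0)
  if (any(hyper[c(2, 3, 4)] <= 0)) stop("kappa0, sigma02, nu0 must be positive")
  mu <- hyper[[1]]; kappa <- hyper[[2]]; s2 <- hyper[[3]]; nu <- hyper[[4]]
  ll <- 0
  for (xi in x) {
    scale2 <- s2 * (kappa + 1) / kappa
    ll <- ll + stats::dt((xi - mu) / sqrt(scale2), df = nu, log = TRUE) -
      0.5 * log(scale2)
    # conjugate update
    mu_new <- (kappa * mu + xi) / (kappa + 1)
    s2 <- (nu * s2 + kappa * (xi - mu)^2 / (kappa + 1)) / (nu + 1)
    mu <- mu_new
    kappa <- kappa + 1
    nu <- nu + 1
  }
  ll
}

#' Synapse-density-profile log-likelihood
#'
#' Each type has a characteristic depth distribution of synaptic contact
#' points, modeled as a mixture of at most three Gaussians with a shared
#' variance scale: `sum_j log sum_m pi_m N(g_j | mu_m, sigma2)`.
#'
#' @param points numeric vector of synapse depths (normalized units).
#' @param means mixture component means, length M with `M <= 3`.
#' @param weights mixture weights on the simplex, length M.
#' @param sigma2 shared component variance, positive.
#' @return log-likelihood; 0 for an empty point set.
#' @export
synapse_profile_loglik <- function(points, means, weights, sigma2) {
  m <- length(means)
  if (m > 3) stop("at most 3 mixture components are supported")
  if (length(weights) != m) stop("means and weights must have equal length")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (length(points) == 0) return(0)
  lw <- log(weights)
  comp <- vapply(seq_len(m), function(j)
    lw[j] + stats::dnorm(points, means[j], sqrt(sigma2), log = TRUE),
    numeric(length(points)))
  comp <- matrix(comp, nrow = length(points))
  mx <- apply(comp, 1, max)
  sum(mx + log(rowSums(exp(comp - mx))))
}

# N x N matrix of pairwise log-likelihood terms for a relation at the given
# assignment and component parameters (vectorized; no masking applied).
pairwise_ll_matrix <- function(rel, geometry, labels, comp, vals) {
  D <- geometry$dmat
  switch(rel$kind,
    bernoulli = {
      MU <- comp$mu[labels, labels, drop = FALSE]
      LAM <- comp$lambda[labels, labels, drop = FALSE]
      p <- clamp_prob(1 / (1 + exp((D - MU) / LAM)) * (vals$pmax - vals$pmin) + vals$pmin)
      ifelse(rel$matrix == 1, log(p), log1p(-p))
    },
    poisson = {
      MU <- comp$mu[labels, labels, drop = FALSE]
      RT <- comp$rate[labels, labels, drop = FALSE]
      r <- pmax(1 / (1 + exp((D - MU) / vals$lambda)) * (RT - vals$rate_min) +
                  vals$rate_min, 1e-10)
      rel$matrix * log(r) - r - lgamma(rel$matrix + 1)
    },
    bernoulli_pp = {
      MU <- comp$mu[labels, labels, drop = FALSE]
      PM <- comp$p[labels, labels, drop = FALSE]
      p <- clamp_prob(1 / (1 + exp((D - MU) / vals$lambda)) * (PM - vals$pmin) + vals$pmin)
      ifelse(rel$matrix == 1, log(p), log1p(-p))
    })
}

#' Log-likelihood of one relation
#'
#' Sum of pairwise observation log-likelihoods over observed (unmasked),
#' off-diagonal pairs. Directed relations iterate ordered pairs; undirected
#' relations iterate unordered pairs. Self-pairs are always excluded.
#'
#' @param rel a `ddsbm_relation`.
#' @param geometry a `ddsbm_geometry` over the same entities.
#' @param labels integer type assignment.
#' @param comp component parameter tables (K x K matrices) for this
#'   relation, named per the observation model.
#' @param vals current global parameter values, as returned by the hyper
#'   spec (for `"bernoulli"`: `pmax`, `pmin`; for `"poisson"`: `lambda`,
#'   `rate_min`; for `"bernoulli_pp"`: `lambda`, `pmin`).
#' @return scalar log-likelihood; 0 if every pair is masked out.
#' @export
relation_loglik <- function(rel, geometry, labels, comp, vals) {
  n <- nrow(rel$matrix)
  if (length(labels) != n || nrow(geometry$dmat) != n)
    stop("dimension mismatch between relation, geometry and labels")
  ll <- pairwise_ll_matrix(rel, geometry, labels, comp, vals)
  keep <- rel$mask
  diag(keep) <- FALSE
  if (!rel$directed) keep <- keep & upper.tri(keep)
  sum(ll[keep])
}

# Sum of component-parameter log-priors for one relation. For undirected
# relations only the upper triangle (including the diagonal) is counted:
# eta_mn and eta_nm are the same stored parameter.
eta_log_prior_sum <- function(rel, comp, spec, vals) {
  if (!is.null(spec$eta_fixed)) return(0)
  K <- nrow(comp[[1]])
  sel <- if (rel$directed) matrix(TRUE, K, K) else upper.tri(comp[[1]], diag = TRUE)
  switch(spec$kind,
    bernoulli = sum(eta_log_prior_logistic(comp$mu[sel], comp$lambda[sel],
                                           vals$mu_hp, vals$lambda_hp)),
    poisson = sum(stats::dexp(comp$mu[sel], 1 / vals$mu_hp, log = TRUE)) +
      sum(stats::dexp(comp$rate[sel] - spec$rate_min,
                      1 / vals$ratescale_hp, log = TRUE)),
    bernoulli_pp = sum(stats::dexp(comp$mu[sel], 1 / vals$mu_hp, log = TRUE)) +
      sum(percomp_pmax_log_prior(comp$p[sel], vals$alpha_hp, vals$beta_hp,
                                 vals$pmin)))
}

# Feature-model log-likelihood (soma depths collapsed per type, synapse
# profiles at the state's mixture parameters). Missing features contribute 0.
feature_loglik <- function(data, state) {
  ll <- 0
  if (!is.null(data$soma_depth)) {
    for (k in seq_len(state$K))
      ll <- ll + soma_depth_loglik(data$soma_depth[state$labels == k],
                                   data$soma_hyper)
  }
  if (!is.null(data$synapse_depths) && !is.null(state$profile)) {
    s2 <- data$profile_sigma2_grid[state$profile$sigma2_idx]
    for (k in seq_len(state$K)) {
      pts <- unlist(data$synapse_depths[state$labels == k], use.names = FALSE)
      ll <- ll + synapse_profile_loglik(pts, state$profile$means[k, ],
                                        state$profile$weights[k, ], s2)
    }
  }
  ll
}

# Log-prior of synapse-profile mixture parameters (means Gaussian, weights
# uniform Dirichlet) -- constant terms kept so scores are comparable.
profile_log_prior <- function(data, state) {
  if (is.null(data$synapse_depths) || is.null(state$profile)) return(0)
  sum(stats::dnorm(state$profile$means, PROFILE_MEAN_MU0,
                   sqrt(PROFILE_MEAN_TAU2), log = TRUE))
}

PROFILE_MEAN_MU0 <- 0.5
PROFILE_MEAN_TAU2 <- 0.25

# Likelihood and prior parts of the unnormalized log posterior, separated so
# annealing can temper the likelihood only.
score_parts <- function(data, state) {
  lik <- 0
  prior <- 0
  for (q in seq_along(data$relations)) {
    rel <- data$relations[[q]]
    spec <- data$hyper[[q]]
    vals <- hyper_values(spec, state$hyper_idx[[q]])
    lik <- lik + relation_loglik(rel, data$geometry, state$labels,
                                 state$comps[[q]], vals)
    prior <- prior + eta_log_prior_sum(rel, state$comps[[q]], spec, vals) +
      grid_log_prior(spec)
  }
  lik <- lik + feature_loglik(data, state)
  alpha <- data$alpha_grid[state$alpha_idx]
  prior <- prior + crp_log_prior(state$labels, alpha) -
    log(length(data$alpha_grid)) + profile_log_prior(data, state)
  list(lik = lik, prior = prior)
}

#' Unnormalized log posterior score of a model state
#'
#' Sum over relations of the data log-likelihood, plus feature-model
#' log-likelihoods, component-parameter log-priors, the CRP partition
#' log-prior, and the uniform hyperparameter grid log-priors. With a
#' temperature `T > 1` only the likelihood terms are divided by `T`; the
#' priors are never tempered, so annealing does not flatten the CRP's
#' preference over type counts.
#'
#' @param data a `ddsbm_data`.
#' @param state a `ddsbm_state`.
#' @param temperature annealing temperature, at least 1.
#' @return scalar log score.
#' @export
joint_log_score <- function(data, state, temperature = 1) {
  if (temperature < 1) stop("temperature must be >= 1")
  parts <- score_parts(data, state)
  parts$lik / temperature + parts$prior
}
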