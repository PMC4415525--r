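# Shared fixture builders; all randomness is seeded by the caller.

# A small undirected bernoulli relation + geometry with hand-set entries.
tiny_bernoulli <- function(n = 4, seed = 1) {
  set.seed(seed)
  pos <- matrix(stats::runif(n * 2, 0, 10), n, 2)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, 0.5)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  list(rel = relation(A, kind = "bernoulli"), geo = entity_geometry(pos))
}

# A ddsbm_data with single-point grids and fixed eta, so the partition
# posterior is exactly enumerable.
fixed_eta_data <- function(n = 5, seed = 2, alpha = 1,
                           mu = 4, lambda = 1.5, pmax = 0.9, pmin = 0.05) {
  set.seed(seed)
  sim <- gen_dd_sbm(n, 2, seed = seed)
  spec <- hyper_spec("bernoulli", mu_hp = mu, lambda_hp = lambda,
                     pmax = pmax, pmin = pmin,
                     eta_fixed = list(mu = mu, lambda = lambda))
  ddsbm_data(sim$relation, sim$geometry, hyper = list(spec),
             alpha_grid = alpha)
}

# Exact log posterior over all set partitions of the data's entities
# (fixed-eta model): CRP prior + relation log-likelihood, normalized.
enumerate_partition_posterior <- function(data) {
  stopifnot(length(data$alpha_grid) == 1)
  spec <- data$hyper[[1]]
  stopifnot(!is.null(spec$eta_fixed))
  parts <- ddsbm:::enumerate_partitions(data$n)
  idx <- vapply(ddsbm:::grid_sizes(spec), function(m) 1L, integer(1))
  vals <- ddsbm:::hyper_values(spec, idx)
  lp <- vapply(parts, function(lab) {
    K <- max(lab)
    comp <- list(mu = matrix(spec$eta_fixed$mu, K, K),
                 lambda = matrix(spec$eta_fixed$lambda, K, K))
    crp_log_prior(lab, data$alpha_grid[1]) +
      relation_loglik(data$relations[[1]], data$geometry, lab, comp, vals)
  }, numeric(1))
  w <- exp(lp - max(lp))
  list(partitions = parts, prob = w / sum(w))
}

partition_key <- function(labels) paste(canonicalize_labels(labels)$labels,
                                        collapse = ".")

# Literal double-loop relation log-likelihood oracle (independent of the
# vectorized implementation).
relation_loglik_bruteforce <- function(rel, geo, labels, comp, vals) {
  n <- nrow(rel$matrix)
  total <- 0
  for (i in seq_len(n)) {
    js <- if (rel$directed) seq_len(n) else if (i < n) (i + 1):n else integer(0)
    for (j in js) {
      if (j == i || !rel$mask[i, j]) next
      m <- labels[i]; nn <- labels[j]
      d <- geo$dmat[i, j]
      obs <- rel$matrix[i, j]
      total <- total + switch(rel$kind,
        bernoulli = {
          p <- (1 / (1 + exp((d - comp$mu[m, nn]) / comp$lambda[m, nn]))) *
            (vals$pmax - vals$pmin) + vals$pmin
          p <- min(max(p, 1e-12), 1 - 1e-12)
          if (obs == 1) log(p) else log(1 - p)
        },
        poisson = {
          r <- (1 / (1 + exp((d - comp$mu[m, nn]) / vals$lambda))) *
            (comp$rate[m, nn] - vals$rate_min) + vals$rate_min
          dpois(obs, max(r, 1e-10), log = TRUE)
        },
        bernoulli_pp = {
          p <- (1 / (1 + exp((d - comp$mu[m, nn]) / vals$lambda))) *
            (comp$p[m, nn] - vals$pmin) + vals$pmin
          p <- min(max(p, 1e-12), 1 - 1e-12)
          if (obs == 1) log(p) else log(1 - p)
        })
    }
  }
  total
}

# Balanced labeled fixture for metric perturbation studies.
balanced_labels <- function(k = 20, per = 20) rep(seq_len(k), each = per)
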