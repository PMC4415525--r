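#' Inference configuration
#'
#' Defaults follow the reference fitting procedure: likelihood annealing
#' from `T = 64` down to `T = 1` over 900 iterations, 100 further
#' iterations at `T = 1`, and 20 independent chains whose final states are
#' pooled as posterior samples.
#'
#' @param n_iters_anneal iterations over which the temperature decays.
#' @param n_iters_post iterations at `T = 1` after annealing.
#' @param T_start,T_end annealing endpoints, `T_start >= T_end >= 1`.
#' @param n_chains number of independent chains.
#' @param n_aux auxiliary (ephemeral) classes instantiated per entity
#'   update in the assignment Gibbs sweep; must be at least 1 or new
#'   classes would be unreachable.
#' @param slice_width_fraction initial slice width for component-parameter
#'   updates, as a fraction of the relevant hyperparameter grid range.
#' @param seed base random seed; chain c runs at `seed + 1000 * (c - 1)`.
#' @return an object of class `ddsbm_config`.
#' @export
inference_config <- function(n_iters_anneal = 900, n_iters_post = 100,
                             T_start = 64, T_end = 1, n_chains = 20,
                             n_aux = 10, slice_width_fraction = 0.1,
                             seed = 1) {
  if (T_start < T_end || T_end < 1) stop("need T_start >= T_end >= 1")
  if (n_chains < 1) stop("need at least one chain")
  if (n_aux < 1) stop("n_aux must be >= 1: new classes would be unreachable")
  structure(list(n_iters_anneal = n_iters_anneal, n_iters_post = n_iters_post,
                 T_start = T_start, T_end = T_end, n_chains = n_chains,
                 n_aux = n_aux, slice_width_fraction = slice_width_fraction,
                 seed = seed),
            class = "ddsbm_config")
}

#' Annealing temperature schedule
#'
#' Geometric interpolation from `T_start` at iteration 0 to `T_end` at
#' `n_iters_anneal`, constant afterwards. Only the likelihood is tempered.
#'
#' @param iter iteration counter, nonnegative.
#' @param config a `ddsbm_config`.
#' @return temperature, monotone non-increasing in `iter`.
#' @export
temperature_at <- function(iter, config) {
  if (config$n_iters_anneal <= 0) return(config$T_end)
  frac <- pmin(iter / config$n_iters_anneal, 1)
  config$T_start * (config$T_end / config$T_start)^frac
}

kind_code <- function(kind) switch(kind, bernoulli = 1L, poisson = 2L,
                                   bernoulli_pp = 3L)

second_par <- function(kind) switch(kind, bernoulli = "lambda",
                                    poisson = "rate", bernoulli_pp = "p")

# Draw m iid component-parameter values from the prior at current hyper
# values. Returns a named list of numeric vectors.
draw_eta <- function(spec, vals, m) {
  if (!is.null(spec$eta_fixed))
    return(lapply(spec$eta_fixed, rep, m))
  switch(spec$kind,
    bernoulli = list(mu = stats::rexp(m, 1 / vals$mu_hp),
                     lambda = stats::rexp(m, 1 / vals$lambda_hp)),
    poisson = list(mu = stats::rexp(m, 1 / vals$mu_hp),
                   rate = spec$rate_min + stats::rexp(m, 1 / vals$ratescale_hp)),
    bernoulli_pp = list(mu = stats::rexp(m, 1 / vals$mu_hp),
                        p = vals$pmin + (1 - vals$pmin) *
                          stats::rbeta(m, vals$alpha_hp, vals$beta_hp)))
}

# K x K component tables drawn from the prior (symmetric if undirected).
draw_comp_tables <- function(spec, vals, K, directed) {
  draws <- draw_eta(spec, vals, K * K)
  out <- lapply(draws, function(v) matrix(v, K, K))
  if (!directed)
    out <- lapply(out, function(M) { M[lower.tri(M)] <- t(M)[lower.tri(M)]; M })
  out
}

# Sample a partition of n entities from the CRP.
crp_sample <- function(n, alpha) {
  labels <- integer(n)
  labels[1] <- 1L
  K <- 1L
  for (i in seq_len(n)[-1]) {
    w <- crp_conditional(tabulate(labels[seq_len(i - 1)], K), alpha)
    k <- sample.int(K + 1L, 1, prob = w)
    labels[i] <- k
    if (k > K) K <- k
  }
  labels
}

# Random initial state: assignment from the CRP prior at the largest gridded
# alpha (a deliberately over-partitioned start: consolidation toward
# structure mixes far better than nucleation out of a collapsed state),
# component parameters and hyperparameter indices from their priors.
init_state <- function(data, config) {
  alpha_idx <- which.max(data$alpha_grid)
  labels <- crp_sample(data$n, data$alpha_grid[alpha_idx])
  K <- max(labels)
  hyper_idx <- lapply(data$hyper, function(s)
    vapply(grid_sizes(s), function(m) sample.int(m, 1), integer(1)))
  comps <- vector("list", length(data$relations))
  for (q in seq_along(data$relations)) {
    spec <- data$hyper[[q]]
    comps[[q]] <- draw_comp_tables(spec, hyper_values(spec, hyper_idx[[q]]), K,
                                   data$relations[[q]]$directed)
  }
  profile <- NULL
  if (!is.null(data$synapse_depths)) {
    M <- data$profile_m
    profile <- list(
      means = matrix(stats::rnorm(K * M, PROFILE_MEAN_MU0,
                                  sqrt(PROFILE_MEAN_TAU2)), K, M),
      weights = rdirichlet_ones(K, M),
      sigma2_idx = sample.int(length(data$profile_sigma2_grid), 1))
  }
  structure(list(labels = labels, K = K, comps = comps, hyper_idx = hyper_idx,
                 alpha_idx = alpha_idx, profile = profile,
                 temperature = config$T_start),
            class = "ddsbm_state")
}

rdirichlet_ones <- function(n, m) {
  g <- matrix(stats::rgamma(n * m, 1), n, m)
  g / rowSums(g)
}

# Posterior-predictive log-density of one depth given the depths already in
# a type (collapsed Normal/scaled-inverse-chi-squared model).
soma_pred_logdens <- function(s, members, hyper) {
  mu <- hyper[[1]]; kappa <- hyper[[2]]; s2 <- hyper[[3]]; nu <- hyper[[4]]
  for (xi in members[!is.na(members)]) {
    mu_new <- (kappa * mu + xi) / (kappa + 1)
    s2 <- (nu * s2 + kappa * (xi - mu)^2 / (kappa + 1)) / (nu + 1)
    mu <- mu_new; kappa <- kappa + 1; nu <- nu + 1
  }
  scale2 <- s2 * (kappa + 1) / kappa
  stats::dt((s - mu) / sqrt(scale2), df = nu, log = TRUE) - 0.5 * log(scale2)
}

# Drop class k from the state (must be empty), compacting labels.
drop_class <- function(state, k) {
  keep <- setdiff(seq_len(state$K), k)
  for (q in seq_along(state$comps))
    state$comps[[q]] <- lapply(state$comps[[q]],
                               function(M) M[keep, keep, drop = FALSE])
  if (!is.null(state$profile)) {
    state$profile$means <- state$profile$means[keep, , drop = FALSE]
    state$profile$weights <- state$profile$weights[keep, , drop = FALSE]
  }
  state$labels <- ifelse(state$labels > k, state$labels - 1L, state$labels)
  state$K <- state$K - 1L
  state
}

sample_log_weights <- function(logw) {
  logw[is.na(logw)] <- -Inf
  m <- max(logw)
  if (!is.finite(m)) return(sample.int(length(logw), 1))
  w <- exp(logw - m)
  sample.int(length(w), 1, prob = w)
}

#' Assignment Gibbs kernel (structural kernel)
#'
#' One full sweep over entities. The likelihood model is non-conjugate, so
#' the conditional over classes is handled with an auxiliary-variable
#' scheme: for each entity, `n_aux` ephemeral classes are instantiated with
#' component (and feature-model) parameters drawn from their priors; the
#' entity is then reassigned with weight `m_k * L_k^(1/T)` for each
#' occupied class and `(alpha / n_aux) * L_k^(1/T)` for each ephemeral
#' class. A singleton entity's own class is retained as the first
#' ephemeral class. Empty classes are removed after every entity update,
#' so labels stay contiguous.
#'
#' @param state a `ddsbm_state`.
#' @param data a `ddsbm_data`.
#' @param config a `ddsbm_config`.
#' @return updated state.
#' @export
kernel_assignments <- function(state, data, config) {
  if (use_fast_path(data))
    return(kernel_assignments_cpp(state, data, config))
  kernel_assignments_r(state, data, config)
}

# Fast path applies when no feature models are attached; the compiled sweep
# implements the identical auxiliary-variable scan.
use_fast_path <- function(data) {
  is.null(data$soma_depth) && is.null(data$synapse_depths)
}

# Relation views handed to the compiled sweeps.
build_cpp_rels <- function(state, data) {
  lapply(seq_along(data$relations), function(q) {
    rel <- data$relations[[q]]
    spec <- data$hyper[[q]]
    vals <- hyper_values(spec, state$hyper_idx[[q]])
    p2 <- second_par(spec$kind)
    prior <- switch(spec$kind,
      bernoulli = c(vals$mu_hp, vals$lambda_hp, 0, 0),
      poisson = c(vals$mu_hp, vals$ratescale_hp, 0, 0),
      bernoulli_pp = c(vals$mu_hp, 0, vals$alpha_hp, vals$beta_hp))
    fixed <- !is.null(spec$eta_fixed)
    list(matrix = rel$matrix, dmat = data$geometry$dmat, mask = rel$mask,
         directed = rel$directed, kind = kind_code(spec$kind),
         theta = theta_vec(spec, vals),
         p1 = state$comps[[q]]$mu, p2 = state$comps[[q]][[p2]],
         prior = prior, fixed = fixed,
         fx = if (fixed) c(spec$eta_fixed$mu, spec$eta_fixed[[p2]])
              else c(0, 0))
  })
}

kernel_assignments_cpp <- function(state, data, config) {
  out <- cpp_sweep_assignments(state$labels, state$K,
                               build_cpp_rels(state, data),
                               data$alpha_grid[state$alpha_idx],
                               state$temperature, config$n_aux)
  state$labels <- as.integer(out$labels)
  state$K <- as.integer(out$K)
  for (q in seq_along(data$relations)) {
    p2 <- second_par(data$hyper[[q]]$kind)
    state$comps[[q]]$mu <- out$comps[[q]]$p1
    state$comps[[q]][[p2]] <- out$comps[[q]]$p2
  }
  state
}

kernel_assignments_r <- function(state, data, config) {
  n_aux <- config$n_aux
  alpha <- data$alpha_grid[state$alpha_idx]
  Tt <- state$temperature
  nrel <- length(data$relations)
  D <- data$geometry$dmat
  s2_prof <- if (!is.null(state$profile))
    data$profile_sigma2_grid[state$profile$sigma2_idx] else NULL
  for (i in seq_len(data$n)) {
    K <- state$K
    k_old <- state$labels[i]
    lab0 <- state$labels
    lab0[i] <- 0L
    sizes <- tabulate(lab0, K)
    singleton <- sizes[k_old] == 0L
    n_fresh <- if (singleton) n_aux - 1L else n_aux
    Kt <- K + n_fresh
    # extended component tables: rows/cols K+1..Kt drawn from the prior
    exts <- vector("list", nrel)
    ll <- numeric(Kt)
    for (q in seq_len(nrel)) {
      rel <- data$relations[[q]]
      spec <- data$hyper[[q]]
      vals <- hyper_values(spec, state$hyper_idx[[q]])
      p2 <- second_par(spec$kind)
      ext <- list()
      for (nm in c("mu", p2)) {
        fresh <- matrix(draw_eta(spec, vals, Kt * Kt)[[nm]], Kt, Kt)
        if (!rel$directed)
          fresh[lower.tri(fresh)] <- t(fresh)[lower.tri(fresh)]
        fresh[seq_len(K), seq_len(K)] <- state$comps[[q]][[nm]]
        ext[[nm]] <- fresh
      }
      exts[[q]] <- ext
      ll <- ll + cpp_entity_class_ll(i, lab0, Kt, rel$matrix, D, rel$mask,
                                     kind_code(spec$kind), ext$mu, ext[[p2]],
                                     theta_vec(spec, vals), rel$directed)
    }
    prof_ext <- NULL
    if (!is.null(state$profile)) {
      M <- data$profile_m
      prof_ext <- list(
        means = rbind(state$profile$means,
                      matrix(stats::rnorm(n_fresh * M, PROFILE_MEAN_MU0,
                                          sqrt(PROFILE_MEAN_TAU2)),
                             n_fresh, M)),
        weights = rbind(state$profile$weights, rdirichlet_ones(n_fresh, M)))
      gi <- data$synapse_depths[[i]]
      if (length(gi))
        for (k in seq_len(Kt))
          ll[k] <- ll[k] + synapse_profile_loglik(gi, prof_ext$means[k, ],
                                                  prof_ext$weights[k, ], s2_prof)
    }
    if (!is.null(data$soma_depth) && !is.na(data$soma_depth[i])) {
      si <- data$soma_depth[i]
      for (k in seq_len(Kt)) {
        members <- if (k <= K) data$soma_depth[lab0 == k] else numeric(0)
        ll[k] <- ll[k] + soma_pred_logdens(si, members, data$soma_hyper)
      }
    }
    logw <- ll / Tt
    logw[seq_len(K)] <- logw[seq_len(K)] +
      ifelse(sizes > 0, log(sizes), log(alpha / n_aux))
    if (n_fresh > 0)
      logw[(K + 1):Kt] <- logw[(K + 1):Kt] + log(alpha / n_aux)
    k_new <- sample_log_weights(logw)
    if (k_new > K) {
      # promote the chosen ephemeral class to a real one
      for (q in seq_len(nrel)) {
        for (nm in names(state$comps[[q]])) {
          M <- matrix(0, K + 1, K + 1)
          M[seq_len(K), seq_len(K)] <- state$comps[[q]][[nm]]
          M[K + 1, seq_len(K)] <- exts[[q]][[nm]][k_new, seq_len(K)]
          M[seq_len(K), K + 1] <- exts[[q]][[nm]][seq_len(K), k_new]
          M[K + 1, K + 1] <- exts[[q]][[nm]][k_new, k_new]
          state$comps[[q]][[nm]] <- M
        }
      }
      if (!is.null(state$profile)) {
        state$profile$means <- rbind(state$profile$means,
                                     prof_ext$means[k_new, ])
        state$profile$weights <- rbind(state$profile$weights,
                                       prof_ext$weights[k_new, ])
      }
      state$K <- K + 1L
      k_new <- K + 1L
    }
    state$labels[i] <- k_new
    if (singleton && k_new != k_old) state <- drop_class(state, k_old)
  }
  state
}

# Univariate slice sampler with stepping out and shrinkage (bounded domain).
slice_sample1 <- function(x0, logf, w, lower = 1e-9, upper = Inf,
                          max_step = 16) {
  f0 <- logf(x0)
  if (!is.finite(f0)) return(x0)
  y <- f0 - stats::rexp(1)
  L <- x0 - w * stats::runif(1)
  R <- L + w
  L <- max(L, lower)
  R <- min(R, upper)
  j <- max_step
  while (j > 0 && L > lower && logf(L) > y) {
    L <- max(L - w, lower); j <- j - 1
  }
  j <- max_step
  while (j > 0 && R < upper && logf(R) > y) {
    R <- min(R + w, upper); j <- j - 1
  }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# Log-prior of a single component parameter, by name.
single_eta_log_prior <- function(nm, x, spec, vals) {
  switch(spec$kind,
    bernoulli = if (nm == "mu") stats::dexp(x, 1 / vals$mu_hp, log = TRUE)
                else stats::dexp(x, 1 / vals$lambda_hp, log = TRUE),
    poisson = if (nm == "mu") stats::dexp(x, 1 / vals$mu_hp, log = TRUE)
              else stats::dexp(x - spec$rate_min, 1 / vals$ratescale_hp,
                               log = TRUE),
    bernoulli_pp = if (nm == "mu") stats::dexp(x, 1 / vals$mu_hp, log = TRUE)
                   else percomp_pmax_log_prior(x, vals$alpha_hp, vals$beta_hp,
                                               vals$pmin))
}

# Slice width and domain for a single component parameter. Width is a
# fraction of the hyperparameter grid range, falling back to the grid scale
# itself for single-point grids.
grid_width <- function(g, frac) {
  base <- diff(range(g))
  if (base <= 0) base <- max(g)
  frac * base
}

eta_slice_geometry <- function(nm, spec, vals, frac) {
  g <- spec$grids
  switch(spec$kind,
    bernoulli = if (nm == "mu")
        list(w = grid_width(g$mu_hp, frac), lower = 1e-9, upper = Inf)
      else list(w = grid_width(g$lambda_hp, frac), lower = 1e-9, upper = Inf),
    poisson = if (nm == "mu")
        list(w = grid_width(g$mu_hp, frac), lower = 1e-9, upper = Inf)
      else list(w = grid_width(g$ratescale_hp, frac),
                lower = spec$rate_min + 1e-9, upper = Inf),
    bernoulli_pp = if (nm == "mu")
        list(w = grid_width(g$mu_hp, frac), lower = 1e-9, upper = Inf)
      else list(w = frac * (1 - vals$pmin), lower = vals$pmin + 1e-9,
                upper = 1 - 1e-9))
}

#' Component-parameter slice-sampling kernel
#'
#' Conditioned on the assignment vector and hyperparameters, the
#' per-component parameters are independent; each is updated by univariate
#' slice sampling of its tempered conditional (block likelihood divided by
#' the temperature, plus its prior). The initial slice width is a fixed
#' fraction of the hyperparameter grid range, stepped out as needed.
#' Components pinned by `eta_fixed` are left untouched. Also refreshes
#' synapse-profile mixture parameters when profiles are modeled.
#'
#' @inheritParams kernel_assignments
#' @return updated state.
#' @export
kernel_eta <- function(state, data, config) {
  if (use_fast_path(data))
    return(kernel_eta_cpp(state, data, config))
  kernel_eta_r(state, data, config)
}

kernel_eta_cpp <- function(state, data, config) {
  frac <- config$slice_width_fraction
  widths <- vector("list", length(data$relations))
  bounds <- vector("list", length(data$relations))
  for (q in seq_along(data$relations)) {
    spec <- data$hyper[[q]]
    vals <- hyper_values(spec, state$hyper_idx[[q]])
    g1 <- eta_slice_geometry("mu", spec, vals, frac)
    g2 <- eta_slice_geometry(second_par(spec$kind), spec, vals, frac)
    widths[[q]] <- c(g1$w, g2$w)
    bounds[[q]] <- c(g1$lower, min(g1$upper, 1e12),
                     g2$lower, min(g2$upper, 1e12))
  }
  out <- cpp_sweep_eta(state$labels, state$K, build_cpp_rels(state, data),
                       state$temperature, widths, bounds)
  for (q in seq_along(data$relations)) {
    p2 <- second_par(data$hyper[[q]]$kind)
    state$comps[[q]]$mu <- out[[q]]$p1
    state$comps[[q]][[p2]] <- out[[q]]$p2
  }
  state
}

kernel_eta_r <- function(state, data, config) {
  Tt <- state$temperature
  K <- state$K
  D <- data$geometry$dmat
  for (q in seq_along(data$relations)) {
    rel <- data$relations[[q]]
    spec <- data$hyper[[q]]
    if (!is.null(spec$eta_fixed)) next
    vals <- hyper_values(spec, state$hyper_idx[[q]])
    th <- theta_vec(spec, vals)
    kc <- kind_code(spec$kind)
    p2 <- second_par(spec$kind)
    pairs <- if (rel$directed) {
      as.matrix(expand.grid(m = seq_len(K), n = seq_len(K)))
    } else {
      idx <- which(upper.tri(diag(K), diag = TRUE), arr.ind = TRUE)
      cbind(m = idx[, 1], n = idx[, 2])
    }
    comp <- state$comps[[q]]
    for (r in seq_len(nrow(pairs))) {
      m <- pairs[r, 1]; n <- pairs[r, 2]
      for (nm in c("mu", p2)) {
        other_nm <- setdiff(c("mu", p2), nm)
        geomS <- eta_slice_geometry(nm, spec, vals, config$slice_width_fraction)
        cur <- comp[[nm]][m, n]
        other <- comp[[other_nm]][m, n]
        logf <- if (nm == "mu") {
          function(x) cpp_block_ll(m, n, state$labels, rel$matrix, D, rel$mask,
                                   kc, x, other, th, rel$directed) / Tt +
            single_eta_log_prior(nm, x, spec, vals)
        } else {
          function(x) cpp_block_ll(m, n, state$labels, rel$matrix, D, rel$mask,
                                   kc, other, x, th, rel$directed) / Tt +
            single_eta_log_prior(nm, x, spec, vals)
        }
        new <- slice_sample1(cur, logf, geomS$w, geomS$lower, geomS$upper)
        comp[[nm]][m, n] <- new
        if (!rel$directed) comp[[nm]][n, m] <- new
      }
    }
    state$comps[[q]] <- comp
  }
  if (!is.null(state$profile)) state <- update_profile(state, data)
  state
}

# Data-augmented Gibbs refresh of synapse-profile mixture parameters: latent
# component indicators, then conjugate Normal means and Dirichlet weights.
# The tempered likelihood is honored by raising responsibilities to 1/T.
update_profile <- function(state, data) {
  M <- data$profile_m
  s2 <- data$profile_sigma2_grid[state$profile$sigma2_idx]
  Tt <- state$temperature
  for (k in seq_len(state$K)) {
    pts <- unlist(data$synapse_depths[state$labels == k], use.names = FALSE)
    if (length(pts) == 0) {
      state$profile$means[k, ] <- stats::rnorm(M, PROFILE_MEAN_MU0,
                                               sqrt(PROFILE_MEAN_TAU2))
      state$profile$weights[k, ] <- rdirichlet_ones(1, M)
      next
    }
    mu <- state$profile$means[k, ]
    wts <- state$profile$weights[k, ]
    lp <- vapply(seq_len(M), function(j)
      (log(wts[j]) + stats::dnorm(pts, mu[j], sqrt(s2), log = TRUE)) / Tt,
      numeric(length(pts)))
    lp <- matrix(lp, nrow = length(pts))
    pr <- exp(lp - apply(lp, 1, max))
    pr <- pr / rowSums(pr)
    z <- vapply(seq_len(nrow(pr)), function(r)
      sample.int(M, 1, prob = pr[r, ]), integer(1))
    counts <- tabulate(z, M)
    for (j in seq_len(M)) {
      xj <- pts[z == j]
      prec <- 1 / PROFILE_MEAN_TAU2 + length(xj) / (s2 * Tt)
      mean_post <- (PROFILE_MEAN_MU0 / PROFILE_MEAN_TAU2 +
                      sum(xj) / (s2 * Tt)) / prec
      state$profile$means[k, j] <- stats::rnorm(1, mean_post, sqrt(1 / prec))
    }
    g <- stats::rgamma(M, 1 + counts / Tt)
    state$profile$weights[k, ] <- g / sum(g)
  }
  state
}

#' Hyperparameter Gibbs kernel
#'
#' Resamples the gridded global parameters from their exact discrete
#' conditionals. Grids that only enter component-parameter priors (the
#' exponential-prior means) are sampled from prior terms alone; grids that
#' enter the likelihood (ceilings, floors, global length scales, the
#' profile variance scale) are sampled proportional to the tempered
#' likelihood at each grid point. The CRP concentration `alpha` is sampled
#' from its gridded conditional given the current partition.
#'
#' @inheritParams kernel_assignments
#' @return updated state.
#' @export
kernel_hypers <- function(state, data, config) {
  Tt <- state$temperature
  for (q in seq_along(data$relations)) {
    rel <- data$relations[[q]]
    spec <- data$hyper[[q]]
    comp <- state$comps[[q]]
    idx <- state$hyper_idx[[q]]
    K <- state$K
    sel <- if (rel$directed) matrix(TRUE, K, K) else upper.tri(diag(K), diag = TRUE)
    keep <- rel$mask
    diag(keep) <- FALSE
    if (!rel$directed) keep <- keep & upper.tri(keep)
    fixed <- !is.null(spec$eta_fixed)
    if (spec$kind == "bernoulli") {
      if (!fixed) {
        idx["mu_hp"] <- sample_log_weights(vapply(spec$grids$mu_hp, function(g)
          sum(stats::dexp(comp$mu[sel], 1 / g, log = TRUE)), numeric(1)))
        idx["lambda_hp"] <- sample_log_weights(vapply(spec$grids$lambda_hp,
          function(g) sum(stats::dexp(comp$lambda[sel], 1 / g, log = TRUE)),
          numeric(1)))
      }
      # ceiling/floor enter the likelihood: joint scan over candidates
      lab <- state$labels
      MU <- comp$mu[lab, lab, drop = FALSE]
      LAM <- comp$lambda[lab, lab, drop = FALSE]
      pstar <- (1 / (1 + exp((data$geometry$dmat - MU) / LAM)))[keep]
      obs <- rel$matrix[keep]
      combos <- expand.grid(a = seq_along(spec$grids$pmax),
                            b = seq_along(spec$grids$pmin))
      lw <- vapply(seq_len(nrow(combos)), function(r) {
        p <- clamp_prob(pstar * (spec$grids$pmax[combos$a[r]] -
                                   spec$grids$pmin[combos$b[r]]) +
                          spec$grids$pmin[combos$b[r]])
        sum(ifelse(obs == 1, log(p), log1p(-p))) / Tt
      }, numeric(1))
      pick <- sample_log_weights(lw)
      idx["pmax"] <- combos$a[pick]
      idx["pmin"] <- combos$b[pick]
    } else if (spec$kind == "poisson") {
      if (!fixed) {
        idx["mu_hp"] <- sample_log_weights(vapply(spec$grids$mu_hp, function(g)
          sum(stats::dexp(comp$mu[sel], 1 / g, log = TRUE)), numeric(1)))
        idx["ratescale_hp"] <- sample_log_weights(
          vapply(spec$grids$ratescale_hp, function(g)
            sum(stats::dexp(comp$rate[sel] - spec$rate_min, 1 / g, log = TRUE)),
            numeric(1)))
      }
      # global logistic scale enters the likelihood
      lw <- vapply(seq_along(spec$grids$lambda), function(a) {
        v <- hyper_values(spec, replace(idx, "lambda", a))
        relation_loglik(rel, data$geometry, state$labels, comp, v) / Tt
      }, numeric(1))
      idx["lambda"] <- sample_log_weights(lw)
    } else { # bernoulli_pp: mu_hp ties the global scale, so it is in the likelihood
      lw <- vapply(seq_along(spec$grids$mu_hp), function(a) {
        v <- hyper_values(spec, replace(idx, "mu_hp", a))
        relation_loglik(rel, data$geometry, state$labels, comp, v) / Tt +
          if (fixed) 0 else sum(stats::dexp(comp$mu[sel], 1 / v$mu_hp, log = TRUE))
      }, numeric(1))
      idx["mu_hp"] <- sample_log_weights(lw)
      lw <- vapply(seq_along(spec$grids$pmin), function(a) {
        v <- hyper_values(spec, replace(idx, "pmin", a))
        if (any(comp$p <= v$pmin)) return(-Inf)
        relation_loglik(rel, data$geometry, state$labels, comp, v) / Tt +
          if (fixed) 0 else sum(percomp_pmax_log_prior(comp$p[sel], v$alpha_hp,
                                                       v$beta_hp, v$pmin))
      }, numeric(1))
      idx["pmin"] <- sample_log_weights(lw)
      if (!fixed) {
        v0 <- hyper_values(spec, idx)
        idx["alpha_hp"] <- sample_log_weights(vapply(spec$grids$alpha_hp,
          function(a) sum(percomp_pmax_log_prior(comp$p[sel], a, v0$beta_hp,
                                                 v0$pmin)), numeric(1)))
        v0 <- hyper_values(spec, idx)
        idx["beta_hp"] <- sample_log_weights(vapply(spec$grids$beta_hp,
          function(b) sum(percomp_pmax_log_prior(comp$p[sel], v0$alpha_hp, b,
                                                 v0$pmin)), numeric(1)))
      }
    }
    state$hyper_idx[[q]] <- idx
  }
  # CRP concentration
  state$alpha_idx <- sample_log_weights(vapply(data$alpha_grid, function(a)
    crp_log_prior(state$labels, a), numeric(1)))
  # synapse-profile variance scale enters the likelihood
  if (!is.null(state$profile) && length(data$profile_sigma2_grid) > 1) {
    lw <- vapply(seq_along(data$profile_sigma2_grid), function(a) {
      st <- state
      st$profile$sigma2_idx <- a
      feature_loglik(data, st) / Tt
    }, numeric(1))
    state$profile$sigma2_idx <- sample_log_weights(lw)
  }
  state
}

#' Run one annealed MCMC chain
#'
#' Executes `n_iters_anneal + n_iters_post` iterations, each one sweep of
#' the assignment, component-parameter, and hyperparameter kernels in that
#' order, with the temperature following [temperature_at()]. The returned
#' trace holds the untempered joint log score after every iteration.
#'
#' @param data a `ddsbm_data`.
#' @param config a `ddsbm_config`.
#' @param seed integer seed for this chain.
#' @return list with `state` (final, at `T = 1`) and `trace`.
#' @export
run_chain <- function(data, config, seed) {
  set.seed(seed)
  state <- init_state(data, config)
  n_total <- config$n_iters_anneal + config$n_iters_post
  trace <- numeric(n_total)
  for (it in seq_len(n_total)) {
    state$temperature <- max(temperature_at(it, config), 1)
    state <- kernel_assignments(state, data, config)
    state <- kernel_eta(state, data, config)
    state <- kernel_hypers(state, data, config)
    trace[it] <- joint_log_score(data, state, 1)
  }
  state$temperature <- 1
  list(state = state, trace = trace)
}

#' Run multiple independent chains and pool their final states
#'
#' Chains start from different random points (assignment from the CRP
#' prior, parameters from their priors) and are run with the annealing
#' schedule; the final state of each chain is kept as one posterior
#' sample.
#'
#' @inheritParams run_chain
#' @param seed base seed; chain c uses `seed + 1000 * (c - 1)`.
#' @return an object of class `ddsbm_samples`: list with `samples`,
#'   `log_scores` (untempered), `chain_ids`, and `traces`.
#' @export
run_chains <- function(data, config, seed = config$seed) {
  res <- lapply(seq_len(config$n_chains), function(ch)
    run_chain(data, config, seed + 1000L * (ch - 1L)))
  structure(list(samples = lapply(res, `[[`, "state"),
                 log_scores = vapply(res, function(r)
                   joint_log_score(data, r$state, 1), numeric(1)),
                 chain_ids = seq_len(config$n_chains),
                 traces = lapply(res, `[[`, "trace")),
            class = "ddsbm_samples")
}

#' Maximum a posteriori sample
#'
#' The pooled sample with the highest untempered log score; ties break
#' toward the lowest chain id.
#'
#' @param samples a `ddsbm_samples`.
#' @return the MAP `ddsbm_state`.
#' @export
map_sample <- function(samples) {
  if (length(samples$samples) == 0) stop("empty sample set")
  samples$samples[[which.max(samples$log_scores)]]
}

#' @export
print.ddsbm_samples <- function(x, ...) {
  ks <- vapply(x$samples, `[[`, integer(1), "K")
  cat(sprintf("<ddsbm_samples> %d samples; K range %d-%d; best log score %.2f\n",
              length(x$samples), min(ks), max(ks), max(x$log_scores)))
  invisible(x)
}
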