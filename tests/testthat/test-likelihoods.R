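test_that("logistic-Bernoulli link matches its closed form", {
  # logistic midpoint and saturation limits
  expect_equal(logistic_bernoulli_prob(5, mu = 5, lambda = 2), 0.5)
  expect_lt(logistic_bernoulli_prob(1e6, mu = 5, lambda = 2, 0.9, 0.01), 0.0101)
  expect_gt(logistic_bernoulli_prob(0, mu = 50, lambda = 1, 0.9, 0.01), 0.8999)
  # independent scalar evaluation of the printed formula
  oracle <- (1 / (1 + exp((12 - 10) / 2))) * (0.9 - 0.01) + 0.01
  expect_equal(logistic_bernoulli_prob(12, 10, 2, 0.9, 0.01), oracle)
  # monotone decreasing in distance for random valid parameters
  set.seed(1)
  for (r in 1:20) {
    mu <- runif(1, 0.1, 20); lam <- runif(1, 0.1, 5)
    pmx <- runif(1, 0.5, 1); pmn <- runif(1, 0, 0.3)
    d <- sort(runif(50, 0, 40))
    p <- logistic_bernoulli_prob(d, mu, lam, pmx, pmn)
    expect_true(all(diff(p) <= 0))
    expect_true(all(p >= pmn & p <= pmx))
  }
  expect_error(logistic_bernoulli_prob(1, 1, lambda = 0), "lambda")
  expect_error(logistic_bernoulli_prob(1, 1, 1, p_max = 0.5, p_min = 0.6), "p_min")
})

test_that("logistic-Bernoulli log-likelihood normalizes and matches the link", {
  expect_equal(logistic_bernoulli_loglik(1, d = 5, mu = 5, lambda = 1), log(0.5))
  set.seed(2)
  for (r in 1:100) {
    d <- runif(1, 0, 30); mu <- runif(1, 0.1, 20); lam <- runif(1, 0.1, 5)
    pmx <- runif(1, 0.5, 1); pmn <- runif(1, 0, 0.3)
    p <- logistic_bernoulli_prob(d, mu, lam, pmx, pmn)
    expect_equal(logistic_bernoulli_loglik(1, d, mu, lam, pmx, pmn), log(p))
    # normalization over the two outcomes
    expect_equal(sum(exp(logistic_bernoulli_loglik(c(0, 1), d, mu, lam, pmx, pmn))), 1)
  }
  expect_error(logistic_bernoulli_loglik(2, 1, 1, 1), "0 or 1")
})

test_that("exponential eta prior is correctly parameterized by its mean", {
  # mode of the exponential is at zero
  expect_equal(eta_log_prior_logistic(0, 0, 5, 3),
               dexp(0, 1 / 5, log = TRUE) + dexp(0, 1 / 3, log = TRUE))
  # numerical quadrature (trapezoid): density integrates to 1
  for (scale in c(0.5, 4, 20)) {
    xs <- seq(0, 50 * scale, length.out = 20001)
    dens <- exp(dexp(xs, 1 / scale, log = TRUE))
    trap <- (sum(dens) - (dens[1] + dens[length(dens)]) / 2) * diff(xs[1:2])
    expect_equal(trap, 1, tolerance = 1e-3)
  }
  # exponential-family closed form under hyperparameter scaling
  expect_equal(eta_log_prior_logistic(2, 1, 10, 10) -
                 eta_log_prior_logistic(2, 1, 5, 5),
               2 * (-log(10) + log(5)) - 3 / 10 + 3 / 5)
  expect_error(eta_log_prior_logistic(-1, 1, 1, 1), "nonnegative")
})

test_that("logistic-Poisson rate and pmf behave per the count model", {
  expect_equal(logistic_poisson_rate(5, mu = 5, r = 20, lambda = 1, r_min = 0.01),
               0.5 * (20 - 0.01) + 0.01)
  expect_lt(logistic_poisson_rate(1e5, 5, 20, 1, 0.01), 0.0101)
  # scalar oracle in the illustrative regime (~20 synapses when close)
  r_star <- 1 / (1 + exp((2 - 5) / 1))
  expect_equal(logistic_poisson_rate(2, 5, 20, 1, 0.01),
               r_star * (20 - 0.01) + 0.01)
  r <- logistic_poisson_rate(3, 5, 20, 1, 0.01)
  expect_equal(logistic_poisson_loglik(0, 3, 5, 20, 1, 0.01), -r)
  # series sum of the pmf at a fixed rate
  expect_equal(sum(exp(logistic_poisson_loglik(0:200, 5, 5, 3, 1, 0.01))), 1,
               tolerance = 1e-10)
  expect_error(logistic_poisson_rate(1, 5, r = 0.005, lambda = 1, r_min = 0.01),
               "exceed")
  expect_error(logistic_poisson_loglik(-1, 1, 5, 20, 1), "nonnegative")
})

test_that("per-component-ceiling Bernoulli sits between its floor and ceiling", {
  expect_equal(percomp_pmax_bernoulli_prob(7, mu = 7, p = 0.8, lambda = 2,
                                           p_min = 0.01),
               0.5 * (0.8 - 0.01) + 0.01)
  expect_error(percomp_pmax_bernoulli_prob(1, 1, p = 1.2, lambda = 1), "0,1")
  # uniform Beta shape: rescaled prior density is constant on (p_min, 1)
  pm <- 0.01
  lp <- percomp_pmax_log_prior(c(0.05, 0.3, 0.9), 1, 1, pm)
  expect_equal(lp, rep(-log(1 - pm), 3))
  # rescaled Beta prior integrates to 1 by quadrature
  for (sh in list(c(2, 3), c(0.5, 0.5), c(1, 2))) {
    xs <- seq(pm + 1e-6, 1 - 1e-6, length.out = 200001)
    dens <- exp(percomp_pmax_log_prior(xs, sh[1], sh[2], pm))
    expect_equal(sum(dens) * diff(xs[1:2]), 1, tolerance = 2e-3)
  }
})

test_that("collapsed soma-depth marginal matches numerical integration", {
  hyper <- c(mu0 = 0.5, kappa0 = 1, sigma02 = 0.04, nu0 = 2)
  expect_equal(soma_depth_loglik(numeric(0), hyper), 0)
  # single point: 2-D numerical integration over (mean, variance) of the
  # Normal/scaled-inverse-chi-squared model
  x <- 0.62
  mus <- seq(-3, 4, length.out = 2001)
  ls2 <- seq(log(1e-6), log(50), length.out = 2001)
  dinvchisq <- function(s2, nu, tau2)
    exp((nu / 2) * log(nu * tau2 / 2) - lgamma(nu / 2) -
          (nu / 2 + 1) * log(s2) - nu * tau2 / (2 * s2))
  # substitute v = log(sigma2); Jacobian s2
  grid <- outer(mus, exp(ls2), function(m, s2)
    dnorm(x, m, sqrt(s2)) * dnorm(m, hyper[1], sqrt(s2 / hyper[2])) *
      dinvchisq(s2, hyper[4], hyper[3]) * s2)
  marg <- sum(grid) * diff(mus[1:2]) * diff(ls2[1:2])
  expect_equal(soma_depth_loglik(x, hyper), log(marg), tolerance = 5e-3)
  # and the closed-form posterior-predictive t density
  scale2 <- hyper[3] * (hyper[2] + 1) / hyper[2]
  cf <- dt((x - hyper[1]) / sqrt(scale2), df = hyper[4], log = TRUE) -
    0.5 * log(scale2)
  expect_equal(soma_depth_loglik(x, hyper), unname(cf))
  # exchangeability: order of depths is irrelevant
  set.seed(3)
  xs <- runif(8)
  expect_equal(soma_depth_loglik(xs, hyper), soma_depth_loglik(rev(xs), hyper))
  expect_equal(soma_depth_loglik(xs, hyper),
               soma_depth_loglik(sample(xs), hyper))
  # NA depths are unobserved
  expect_equal(soma_depth_loglik(c(xs, NA), hyper), soma_depth_loglik(xs, hyper))
})

test_that("synapse-profile mixture log-likelihood is exact", {
  # single component reduces to a plain Gaussian
  set.seed(4)
  pts <- rnorm(20, 0.5, 0.1)
  expect_equal(synapse_profile_loglik(pts, 0.5, 1, 0.01),
               sum(dnorm(pts, 0.5, 0.1, log = TRUE)))
  # duplicating the point set doubles the log-likelihood
  m <- c(0.2, 0.5, 0.8); w <- c(0.2, 0.5, 0.3)
  l1 <- synapse_profile_loglik(pts, m, w, 0.02)
  expect_equal(synapse_profile_loglik(c(pts, pts), m, w, 0.02), 2 * l1)
  # direct-summation oracle on random instances
  for (r in 1:50) {
    M <- sample(1:3, 1)
    mm <- runif(M); ww <- rgamma(M, 1); ww <- ww / sum(ww)
    s2 <- runif(1, 0.005, 0.5)
    g <- runif(6)
    direct <- sum(log(vapply(g, function(x)
      sum(ww * dnorm(x, mm, sqrt(s2))), numeric(1))))
    expect_equal(synapse_profile_loglik(g, mm, ww, s2), direct)
  }
  expect_error(synapse_profile_loglik(1, rep(0.5, 4), rep(0.25, 4), 1), "at most 3")
  expect_error(synapse_profile_loglik(1, c(0.5, 0.6), c(0.7, 0.7), 1), "sum to 1")
})

test_that("relation log-likelihood equals a literal double-loop oracle", {
  set.seed(5)
  for (r in 1:12) {
    n <- sample(4:8, 1)
    directed <- r %% 2 == 0
    kind <- c("bernoulli", "poisson", "bernoulli_pp")[(r %% 3) + 1]
    K <- sample(2:3, 1)
    labels <- sample(seq_len(K), n, replace = TRUE)
    labels <- canonicalize_labels(labels)$labels
    K <- max(labels)
    pos <- matrix(runif(n * 2, 0, 10), n, 2)
    geo <- entity_geometry(pos)
    A <- if (kind == "poisson") matrix(rpois(n * n, 2), n, n)
         else matrix(rbinom(n * n, 1, 0.4), n, n)
    diag(A) <- 0
    if (!directed) A[lower.tri(A)] <- t(A)[lower.tri(A)]
    storage.mode(A) <- "double"
    mask <- matrix(runif(n * n) < 0.8, n, n)
    if (!directed) mask <- mask & t(mask)
    diag(mask) <- TRUE
    rel <- relation(A, kind = kind, directed = directed, mask = mask)
    comp <- switch(kind,
      bernoulli = list(mu = matrix(runif(K * K, 1, 8), K, K),
                       lambda = matrix(runif(K * K, 0.5, 3), K, K)),
      poisson = list(mu = matrix(runif(K * K, 1, 8), K, K),
                     rate = matrix(runif(K * K, 1, 10), K, K)),
      bernoulli_pp = list(mu = matrix(runif(K * K, 1, 8), K, K),
                          p = matrix(runif(K * K, 0.2, 0.95), K, K)))
    if (!directed) comp <- lapply(comp, function(M) {
      M[lower.tri(M)] <- t(M)[lower.tri(M)]; M
    })
    vals <- switch(kind,
      bernoulli = list(pmax = 0.9, pmin = 0.02),
      poisson = list(lambda = 1.2, rate_min = 0.01),
      bernoulli_pp = list(lambda = 1.5, pmin = 0.01))
    expect_equal(relation_loglik(rel, geo, labels, comp, vals),
                 relation_loglik_bruteforce(rel, geo, labels, comp, vals))
  }
})

test_that("masked-out relations contribute nothing", {
  fx <- tiny_bernoulli(5, seed = 6)
  rel <- fx$rel
  rel$mask[] <- FALSE
  comp <- list(mu = matrix(3, 1, 1), lambda = matrix(1, 1, 1))
  expect_equal(relation_loglik(rel, fx$geo, rep(1L, 5), comp,
                               list(pmax = 0.9, pmin = 0.01)), 0)
})

test_that("three-node undirected graph equals the hand-summed pairwise terms", {
  pos <- matrix(c(0, 0, 3, 0, 0, 4), 3, 2, byrow = TRUE)
  geo <- entity_geometry(pos)
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  rel <- relation(A, kind = "bernoulli")
  comp <- list(mu = matrix(4, 1, 1), lambda = matrix(2, 1, 1))
  vals <- list(pmax = 1, pmin = 0)
  # pairs: (1,2) d = 3 linked; (1,3) d = 4 unlinked; (2,3) d = 5 linked
  pfun <- function(d) 1 / (1 + exp((d - 4) / 2))
  hand <- log(pfun(3)) + log1p(-pfun(4)) + log(pfun(5))
  expect_equal(relation_loglik(rel, geo, rep(1L, 3), comp, vals), hand)
})

test_that("joint log score composes likelihood and priors; duplicates double the likelihood", {
  sim <- gen_dd_sbm(12, 2, seed = 8)
  data1 <- ddsbm_data(sim$relation, sim$geometry)
  data2 <- ddsbm_data(list(sim$relation, sim$relation), sim$geometry,
                      hyper = list(hyper_spec("bernoulli"),
                                   hyper_spec("bernoulli")))
  set.seed(9)
  st <- ddsbm:::init_state(data1, inference_config(n_chains = 1))
  st2 <- st
  st2$comps <- list(st$comps[[1]], st$comps[[1]])
  st2$hyper_idx <- list(st$hyper_idx[[1]], st$hyper_idx[[1]])
  p1 <- ddsbm:::score_parts(data1, st)
  p2 <- ddsbm:::score_parts(data2, st2)
  expect_equal(p2$lik, 2 * p1$lik)
  # T = 1 score is likelihood + priors
  expect_equal(joint_log_score(data1, st, 1), p1$lik + p1$prior)
  # tempering divides the likelihood only
  expect_equal(joint_log_score(data1, st, 8), p1$lik / 8 + p1$prior)
  expect_error(joint_log_score(data1, st, 0.5), "temperature")
})

test_that("compiled pairwise kernels agree with the R likelihood", {
  set.seed(10)
  sim <- gen_dd_sbm(10, 2, seed = 10)
  data <- ddsbm_data(sim$relation, sim$geometry)
  rel <- data$relations[[1]]
  labels <- sim$truth$labels
  K <- max(labels)
  comp <- list(mu = matrix(runif(K * K, 1, 8), K, K),
               lambda = matrix(runif(K * K, 0.5, 3), K, K))
  comp <- lapply(comp, function(M) { M[lower.tri(M)] <- t(M)[lower.tri(M)]; M })
  vals <- list(pmax = 0.9, pmin = 0.01)
  # block log-likelihoods partition the full relation log-likelihood
  blocks <- 0
  for (m in 1:K) for (n in m:K)
    blocks <- blocks + ddsbm:::cpp_block_ll(m, n, labels, rel$matrix,
                                            data$geometry$dmat, rel$mask, 1L,
                                            comp$mu[m, n], comp$lambda[m, n],
                                            c(0.9, 0.01), FALSE)
  expect_equal(blocks, relation_loglik(rel, data$geometry, labels, comp, vals))
  # entity-class log-likelihood equals the delta of full log-likelihoods
  i <- 4L
  lab0 <- labels
  lab0[i] <- 0L
  ll <- ddsbm:::cpp_entity_class_ll(i, lab0, K, rel$matrix, data$geometry$dmat,
                                    rel$mask, 1L, comp$mu, comp$lambda,
                                    c(0.9, 0.01), FALSE)
  base <- local({
    r2 <- rel
    r2$mask[i, ] <- FALSE
    r2$mask[, i] <- FALSE
    relation_loglik(r2, data$geometry, labels, comp, vals)
  })
  for (k in 1:K) {
    lab_k <- labels
    lab_k[i] <- k
    expect_equal(ll[k],
                 relation_loglik(rel, data$geometry, lab_k, comp, vals) - base)
  }
})
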