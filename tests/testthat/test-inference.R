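test_that("configuration and temperature schedule follow the annealing design", {
  cfg <- inference_config()
  expect_equal(temperature_at(0, cfg), 64)
  expect_equal(temperature_at(900, cfg), 1)
  expect_equal(temperature_at(1000, cfg), 1)
  ts <- temperature_at(0:1000, cfg)
  expect_true(all(diff(ts) <= 1e-12))
  expect_error(inference_config(n_aux = 0), "n_aux")
  expect_error(inference_config(T_start = 1, T_end = 4), "T_start")
  expect_error(inference_config(n_chains = 0), "chain")
})

test_that("chains are reproducible and independent across seeds", {
  sim <- gen_dd_sbm(25, 2, seed = 39)
  data <- ddsbm_data(sim$relation, sim$geometry)
  cfg <- inference_config(n_iters_anneal = 15, n_iters_post = 5,
                          T_start = 1.5, n_chains = 1, seed = 1)
  r1 <- run_chain(data, cfg, seed = 7)
  r2 <- run_chain(data, cfg, seed = 7)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$state$labels, r2$state$labels)
  r3 <- run_chain(data, cfg, seed = 8)
  expect_false(identical(r1$trace, r3$trace))
  expect_true(all(is.finite(r1$trace)))
  # run_chains pools one final state per chain at T = 1
  cfg4 <- inference_config(n_iters_anneal = 10, n_iters_post = 5,
                           T_start = 1.5, n_chains = 4, seed = 2)
  ss <- run_chains(data, cfg4)
  expect_length(ss$samples, 4)
  expect_true(all(vapply(ss$samples, `[[`, numeric(1), "temperature") == 1))
  expect_equal(ss$log_scores,
               vapply(ss$samples, function(s) joint_log_score(data, s),
                      numeric(1)))
})

test_that("map_sample picks the highest score with first-index ties", {
  mk <- function(k) structure(list(labels = c(1L), K = 1L, tag = k),
                              class = "ddsbm_state")
  ss <- structure(list(samples = list(mk(1), mk(2), mk(3)),
                       log_scores = c(-10, -5, -7), chain_ids = 1:3,
                       traces = list()), class = "ddsbm_samples")
  expect_equal(map_sample(ss)$tag, 2)
  ss$log_scores <- c(-5, -5, -5)
  expect_equal(map_sample(ss)$tag, 1)
  ss$samples <- list()
  expect_error(map_sample(ss), "empty")
})

test_that("assignment kernel separates two extreme cliques", {
  # two 10-node groups: within-group edges certain at any distance,
  # between-group edges near-impossible
  n <- 20
  lab_true <- rep(1:2, each = 10)
  set.seed(40)
  pos <- matrix(runif(n * 2, 0, 10), n, 2)
  A <- outer(lab_true, lab_true, "==") * 1
  diag(A) <- 0
  rel <- relation(A, kind = "bernoulli")
  spec <- hyper_spec("bernoulli", mu_hp = 50, lambda_hp = 5,
                     pmax = 0.999, pmin = 0.001)
  data <- ddsbm_data(rel, entity_geometry(pos), hyper = list(spec),
                     alpha_grid = 1)
  cfg <- inference_config(n_iters_anneal = 0, n_iters_post = 1, T_start = 1,
                          n_chains = 1, seed = 1)
  hits <- 0
  for (s in 1:15) {
    set.seed(s)
    st <- ddsbm:::init_state(data, cfg)
    for (it in 1:15) {
      st <- kernel_assignments(st, data, cfg)
      st <- kernel_eta(st, data, cfg)
      st <- kernel_hypers(st, data, cfg)
    }
    if (adjusted_rand_index(st$labels, lab_true) == 1) hits <- hits + 1
  }
  expect_gte(hits, 13)
})

test_that("eta posterior reverts to its prior without incident data", {
  # single-point hyper grids pin the prior; all pairs masked out
  n <- 6
  A <- matrix(0, n, n)
  mask <- matrix(FALSE, n, n)
  diag(mask) <- TRUE
  rel <- relation(A, kind = "bernoulli", mask = mask)
  spec <- hyper_spec("bernoulli", mu_hp = 5, lambda_hp = 2, pmax = 0.9,
                     pmin = 0.01)
  set.seed(41)
  data <- ddsbm_data(rel, entity_geometry(matrix(runif(n * 2), n, 2)),
                     hyper = list(spec), alpha_grid = 1)
  cfg <- inference_config(n_chains = 1, seed = 1)
  st <- ddsbm:::init_state(data, cfg)
  st$labels <- rep(1L, n)
  st$K <- 1L
  st$comps[[1]] <- list(mu = matrix(3, 1, 1), lambda = matrix(1, 1, 1))
  st$temperature <- 1
  mus <- numeric(1500)
  lams <- numeric(1500)
  for (it in seq_len(1500)) {
    st <- kernel_eta(st, data, cfg)
    mus[it] <- st$comps[[1]]$mu[1, 1]
    lams[it] <- st$comps[[1]]$lambda[1, 1]
  }
  thin <- seq(10, 1500, by = 5)
  expect_gt(ks.test(mus[thin], pexp, 1 / 5)$p.value, 0.01)
  expect_gt(ks.test(lams[thin], pexp, 1 / 2)$p.value, 0.01)
})

test_that("slice sampler leaves a known density invariant", {
  set.seed(42)
  logf <- function(x) dexp(x, rate = 1, log = TRUE)
  x <- 1
  draws <- numeric(4000)
  for (i in seq_len(4000)) {
    x <- ddsbm:::slice_sample1(x, logf, w = 1, lower = 1e-12, upper = Inf)
    draws[i] <- x
  }
  expect_gt(ks.test(draws[seq(20, 4000, by = 4)], pexp, 1)$p.value, 0.01)
})

test_that("eta posterior concentrates near truth with abundant data", {
  # all pairs generated at the true eta; posterior mean of mu close to truth
  sim <- gen_dd_sbm(120, 1, seed = 43,
                    eta_truth = list(mu = matrix(5, 1, 1),
                                     lambda = matrix(1, 1, 1)),
                    theta = list(pmax = 0.95, pmin = 0.01))
  spec <- hyper_spec("bernoulli", pmax = 0.95, pmin = 0.01)
  data <- ddsbm_data(sim$relation, sim$geometry, hyper = list(spec),
                     alpha_grid = 1)
  cfg <- inference_config(n_chains = 1, seed = 1)
  set.seed(44)
  st <- ddsbm:::init_state(data, cfg)
  st$labels <- rep(1L, 120)
  st$K <- 1L
  st$comps[[1]] <- list(mu = matrix(2, 1, 1), lambda = matrix(2, 1, 1))
  st$temperature <- 1
  mus <- numeric(300)
  for (it in seq_len(300)) {
    st <- kernel_eta(st, data, cfg)
    st <- kernel_hypers(st, data, cfg)
    mus[it] <- st$comps[[1]]$mu[1, 1]
  }
  post <- mus[101:300]
  expect_lt(abs(mean(post) - 5), 3 * sd(post) + 0.05)
})

test_that("hyperparameter kernel samples exact discrete conditionals", {
  sim <- gen_dd_sbm(15, 2, seed = 45)
  # single-point grids leave the state unchanged
  spec1 <- hyper_spec("bernoulli", mu_hp = 5, lambda_hp = 2, pmax = 0.9,
                      pmin = 0.01)
  data1 <- ddsbm_data(sim$relation, sim$geometry, hyper = list(spec1),
                      alpha_grid = 1)
  cfg <- inference_config(n_chains = 1, seed = 1)
  set.seed(46)
  st <- ddsbm:::init_state(data1, cfg)
  st$temperature <- 1
  st2 <- kernel_hypers(st, data1, cfg)
  expect_identical(st2$hyper_idx, st$hyper_idx)
  expect_identical(st2$alpha_idx, st$alpha_idx)
  # duplicated alpha candidates have identical conditionals: ~50/50
  data2 <- ddsbm_data(sim$relation, sim$geometry, hyper = list(spec1),
                      alpha_grid = c(2, 2))
  set.seed(47)
  st <- ddsbm:::init_state(data2, cfg)
  st$temperature <- 1
  picks <- replicate(2000, kernel_hypers(st, data2, cfg)$alpha_idx)
  p_hat <- mean(picks == 1)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("assignment kernel targets the exact partition posterior (fixed eta)", {
  # N = 5 with pinned component parameters: the posterior over the 52
  # partitions is enumerable; long-run kernel frequencies must match.
  data <- fixed_eta_data(n = 5, seed = 48)
  exact <- enumerate_partition_posterior(data)
  keys <- vapply(exact$partitions, partition_key, character(1))
  cfg <- inference_config(n_chains = 1, n_aux = 3, seed = 1)
  set.seed(49)
  st <- ddsbm:::init_state(data, cfg)
  st$temperature <- 1
  n_sweeps <- 20000
  counts <- setNames(numeric(length(keys)), keys)
  for (it in seq_len(n_sweeps)) {
    st <- kernel_assignments(st, data, cfg)
    k <- partition_key(st$labels)
    counts[k] <- counts[k] + 1
  }
  emp <- counts / n_sweeps
  tv <- 0.5 * sum(abs(emp - exact$prob[match(names(emp), keys)]))
  expect_lt(tv, 0.03)
  # the reference R implementation targets the same posterior
  set.seed(50)
  st <- ddsbm:::init_state(data, cfg)
  st$temperature <- 1
  counts_r <- setNames(numeric(length(keys)), keys)
  for (it in seq_len(6000)) {
    st <- ddsbm:::kernel_assignments_r(st, data, cfg)
    k <- partition_key(st$labels)
    counts_r[k] <- counts_r[k] + 1
  }
  tv_r <- 0.5 * sum(abs(counts_r / 6000 - exact$prob[match(names(counts_r), keys)]))
  expect_lt(tv_r, 0.05)
})

test_that("feature models sharpen type recovery on feature-rich data", {
  sim <- gen_dd_sbm(36, 3, seed = 51)
  ft <- gen_features(sim$truth$labels,
                     depth_params = list(mean = c(0.15, 0.5, 0.85),
                                         sd = c(0.04, 0.04, 0.04)),
                     profile_params = list(
                       means = rbind(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6),
                                     c(0.7, 0.8, 0.9)),
                       weights = matrix(1 / 3, 3, 3), sd = 0.03,
                       n_synapses = 6),
                     seed = 52)
  data <- ddsbm_data(sim$relation, sim$geometry,
                     soma_depth = pmin(pmax(ft$soma_depth, 0), 1),
                     synapse_depths = lapply(ft$synapse_depths,
                                             function(x) pmin(pmax(x, 0), 1)))
  cfg <- inference_config(n_iters_anneal = 25, n_iters_post = 15,
                          T_start = 1.5, n_chains = 3, seed = 3)
  ss <- run_chains(data, cfg)
  mp <- map_sample(ss)
  expect_identical(validate_state(mp, data), character(0))
  expect_gte(adjusted_rand_index(mp$labels, sim$truth$labels), 0.8)
  expect_true(all(is.finite(unlist(ss$traces))))
})
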