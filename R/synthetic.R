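#' Generate data from the distance-dependent stochastic block model
#'
#' Entities are placed i.i.d. uniformly in space, assigned to `k` balanced
#' types (round-robin) or CRP-sampled types, and edges are drawn
#' independently from the logistic-distance Bernoulli (or Poisson) link at
#' the true component parameters.
#'
#' @param n number of entities.
#' @param k number of types, at most `n`.
#' @param layout `"uniform_square"` (2-D unit-free square of side
#'   `side`) or `"uniform_interval"` (1-D).
#' @param eta_truth list with K x K matrices `mu` and `lambda` (Bernoulli)
#'   or `mu` and `rate` (Poisson); defaults to a well-separated
#'   assortative pattern scaled to the layout (see Details).
#' @param theta list of global parameters: Bernoulli `pmax`, `pmin`;
#'   Poisson `lambda`, `rate_min`.
#' @param kind `"bernoulli"` or `"poisson"`.
#' @param side side length of the square (or interval length).
#' @param directed logical.
#' @param crp_alpha if non-`NULL`, type sizes are CRP-sampled at this
#'   concentration instead of balanced.
#' @param seed integer seed.
#' @return list with `relation`, `geometry`, and `truth` (a
#'   `ddsbm_truth`: true labels, parameters, generator family, settings,
#'   seed).
#' @details The default truth realizes the well-separated regime of the
#'   validation experiments: same-type pairs connect on a long length
#'   scale (`mu = 0.7 * side`), different-type pairs only when very close
#'   (`mu = 0.1 * side`), with `lambda = 0.05 * side`, `pmax = 0.95`,
#'   `pmin = 0.01`. The same-type and cross-type connection curves are
#'   nearly disjoint over the typical pairwise-distance range, and edge
#'   density stays moderate (roughly 0.1-0.2 for small K).
#' @export
gen_dd_sbm <- function(n, k, layout = c("uniform_square", "uniform_interval"),
                       eta_truth = NULL, theta = NULL,
                       kind = c("bernoulli", "poisson"), side = 10,
                       directed = FALSE, crp_alpha = NULL, seed = 1) {
  layout <- match.arg(layout)
  kind <- match.arg(kind)
  if (k > n) stop("need k <= n")
  set.seed(seed)
  dims <- if (layout == "uniform_square") 2 else 1
  pos <- matrix(stats::runif(n * dims, 0, side), n, dims)
  geometry <- entity_geometry(pos)
  labels <- if (is.null(crp_alpha)) rep_len(seq_len(k), n)[sample.int(n)]
            else canonicalize_labels(crp_sample(n, crp_alpha))$labels
  k_eff <- max(labels)
  if (is.null(theta))
    theta <- if (kind == "bernoulli") list(pmax = 0.95, pmin = 0.01)
             else list(lambda = 0.1 * side, rate_min = 0.01)
  if (is.null(eta_truth)) {
    mu <- matrix(0.1 * side, k_eff, k_eff)
    diag(mu) <- 0.7 * side
    eta_truth <- if (kind == "bernoulli")
      list(mu = mu, lambda = matrix(0.05 * side, k_eff, k_eff))
    else list(mu = mu, rate = matrix(8, k_eff, k_eff) + diag(8, k_eff))
  }
  D <- geometry$dmat
  MU <- eta_truth$mu[labels, labels, drop = FALSE]
  if (kind == "bernoulli") {
    LAM <- eta_truth$lambda[labels, labels, drop = FALSE]
    P <- 1 / (1 + exp((D - MU) / LAM)) * (theta$pmax - theta$pmin) + theta$pmin
    A <- matrix(stats::rbinom(n * n, 1, P), n, n)
  } else {
    RT <- eta_truth$rate[labels, labels, drop = FALSE]
    R <- 1 / (1 + exp((D - MU) / theta$lambda)) * (RT - theta$rate_min) +
      theta$rate_min
    A <- matrix(stats::rpois(n * n, R), n, n)
  }
  diag(A) <- 0
  if (!directed) A[lower.tri(A)] <- t(A)[lower.tri(A)]
  storage.mode(A) <- "double"
  list(relation = relation(A, kind = kind, directed = directed),
       geometry = geometry,
       truth = new_truth(labels, eta_truth, "dd_sbm",
                         list(layout = layout, side = side, theta = theta,
                              kind = kind, directed = directed), seed))
}

new_truth <- function(labels, params, family, settings, seed) {
  structure(list(labels = labels, params = params, family = family,
                 settings = settings, seed = seed),
            class = "ddsbm_truth")
}

#' Generate data from the plain (non-spatial) stochastic block model
#'
#' Edges are `Bernoulli(p[c_i, c_j])`; distance plays no role.
#'
#' @param n,k entity and type counts.
#' @param p_table K x K matrix of connection probabilities.
#' @param directed logical.
#' @param seed integer seed.
#' @return list with `relation` and `truth`.
#' @export
gen_sbm <- function(n, k, p_table = NULL, directed = FALSE, seed = 1) {
  set.seed(seed)
  if (is.null(p_table)) p_table <- matrix(0.05, k, k) + diag(0.25, k)
  if (any(p_table < 0 | p_table > 1)) stop("probabilities must be in [0,1]")
  labels <- rep_len(seq_len(k), n)[sample.int(n)]
  P <- p_table[labels, labels, drop = FALSE]
  A <- matrix(stats::rbinom(n * n, 1, P), n, n)
  diag(A) <- 0
  if (!directed) A[lower.tri(A)] <- t(A)[lower.tri(A)]
  storage.mode(A) <- "double"
  list(relation = relation(A, kind = "bernoulli", directed = directed),
       truth = new_truth(labels, list(p = p_table), "sbm",
                         list(directed = directed), seed))
}

#' Generate data from the mixed-membership block model
#'
#' Each entity holds a Dirichlet membership vector over `k` roles; for
#' every pair, each endpoint samples a role from its memberships and the
#' edge is Bernoulli at the role-pair probability. There is no single true
#' type per entity, so the truth stores membership vectors and the label
#' slot holds each entity's dominant role.
#'
#' @param n,k entity and role counts (`k >= 2`).
#' @param dirichlet_conc concentration of the membership Dirichlet;
#'   smaller values give nearly single-role entities (recovering the plain
#'   block model in the limit).
#' @param p_table K x K role-pair connection probabilities.
#' @param seed integer seed.
#' @return list with `relation` and `truth` (with `memberships`).
#' @export
gen_mixed_membership <- function(n, k, dirichlet_conc = 0.2, p_table = NULL,
                                 seed = 1) {
  if (k < 2) stop("need k >= 2")
  set.seed(seed)
  if (is.null(p_table)) p_table <- matrix(0.05, k, k) + diag(0.25, k)
  g <- matrix(stats::rgamma(n * k, dirichlet_conc), n, k)
  theta <- g / rowSums(g)
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    # role resampled per pair, per endpoint
    for (j in (i + 1):n) {
      ri <- sample.int(k, 1, prob = theta[i, ])
      rj <- sample.int(k, 1, prob = theta[j, ])
      A[i, j] <- A[j, i] <- stats::rbinom(1, 1, p_table[ri, rj])
    }
  }
  tr <- new_truth(max.col(theta), list(p = p_table), "mixed_membership",
                  list(dirichlet_conc = dirichlet_conc), seed)
  tr$memberships <- theta
  list(relation = relation(A, kind = "bernoulli", directed = FALSE),
       truth = tr)
}

#' Generate data from the latent position cluster model
#'
#' Latent positions come from a Gaussian mixture with `k` clusters; the
#' edge probability is `logistic(intercept - ||z_i - z_j||)`, a decreasing
#' function of latent distance. Type is clustered-but-continuous, the
#' regime in which a discrete block model is misspecified.
#'
#' @param n,k entity and cluster counts.
#' @param dims latent dimensionality.
#' @param cluster_means optional k x dims matrix; defaults to well
#'   separated draws.
#' @param sigma within-cluster standard deviation.
#' @param intercept logistic intercept controlling density.
#' @param seed integer seed.
#' @return list with `relation`, `truth`, and the latent `positions`.
#' @export
gen_latent_position_cluster <- function(n, k, dims = 2, cluster_means = NULL,
                                        sigma = 0.5, intercept = 1, seed = 1) {
  if (dims < 1) stop("need dims >= 1")
  set.seed(seed)
  if (is.null(cluster_means))
    cluster_means <- matrix(stats::rnorm(k * dims, 0, 3), k, dims)
  labels <- rep_len(seq_len(k), n)[sample.int(n)]
  z <- cluster_means[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * dims, 0, sigma), n, dims)
  dz <- as.matrix(stats::dist(z))
  P <- 1 / (1 + exp(-(intercept - dz)))
  A <- matrix(stats::rbinom(n * n, 1, P), n, n)
  diag(A) <- 0
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  storage.mode(A) <- "double"
  out <- list(relation = relation(A, kind = "bernoulli", directed = FALSE),
              truth = new_truth(labels, list(means = cluster_means,
                                             sigma = sigma,
                                             intercept = intercept),
                                "latent_position_cluster", list(dims = dims),
                                seed),
              positions = z)
  out
}

#' Generate per-type feature data (soma depths and synapse profiles)
#'
#' Soma depths are drawn from each type's Gaussian; each entity's synapse
#' depths come from its type's mixture of Gaussians.
#'
#' @param labels true type assignment.
#' @param depth_params list with per-type vectors `mean` and `sd`.
#' @param profile_params list with per-type rows `means` (K x M),
#'   `weights` (K x M), scalar `sd`, and `n_synapses` (count per entity,
#'   scalar or length-N).
#' @param seed integer seed.
#' @return list with `soma_depth` (length N) and `synapse_depths`
#'   (length-N list).
#' @export
gen_features <- function(labels, depth_params, profile_params, seed = 1) {
  set.seed(seed)
  n <- length(labels)
  soma <- stats::rnorm(n, depth_params$mean[labels], depth_params$sd[labels])
  nsyn <- rep_len(profile_params$n_synapses, n)
  syn <- lapply(seq_len(n), function(i) {
    k <- labels[i]
    comp <- sample.int(ncol(profile_params$means), nsyn[i], replace = TRUE,
                       prob = profile_params$weights[k, ])
    stats::rnorm(nsyn[i], profile_params$means[k, comp], profile_params$sd)
  })
  list(soma_depth = soma, synapse_depths = syn)
}

#' Restrict data to a circular window (edge-effect experiment)
#'
#' Keeps only the entities within `radius` of `center` and the induced
#' subgraph: relation matrix, mask, geometry, features, and truth labels
#' are all restricted consistently. Models the reconstruction of a
#' bounded tissue volume, which truncates long-range connections at the
#' boundary.
#'
#' @param sim a list with `relation`, `geometry`, `truth` (as returned by
#'   the generators), optionally `soma_depth` / `synapse_depths`.
#' @param center numeric center of the window.
#' @param radius window radius; `Inf` returns the input.
#' @return the restricted list, plus `kept` (indices of retained
#'   entities).
#' @export
edge_effect_window <- function(sim, center, radius) {
  pos <- sim$geometry$positions
  if (is.null(pos)) stop("geometry has no positions")
  keep <- which(sqrt(rowSums(sweep(pos, 2, center)^2)) <= radius)
  out <- sim
  out$relation$matrix <- sim$relation$matrix[keep, keep, drop = FALSE]
  out$relation$mask <- sim$relation$mask[keep, keep, drop = FALSE]
  out$geometry <- entity_geometry(pos[keep, , drop = FALSE])
  if (!is.null(sim$truth)) {
    out$truth$labels <- sim$truth$labels[keep]
  }
  if (!is.null(sim$soma_depth)) out$soma_depth <- sim$soma_depth[keep]
  if (!is.null(sim$synapse_depths))
    out$synapse_depths <- sim$synapse_depths[keep]
  out$kept <- keep
  out
}

#' Spatial-dependence statistic: variance of the connectivity-distance
#' profile
#'
#' Bins the observed pairs by distance, computes the per-type-pair
#' connection frequency in each bin, and returns the mean (over type
#' pairs) variance of those frequencies across bins, debiased by the
#' estimated within-bin binomial sampling noise
#' (`mean(f (1 - f) / (n - 1))`). The debiasing makes the statistic
#' comparable across window sizes: without it, small windows inflate the
#' raw variance simply because each bin holds fewer pairs.
#' Distance-independent data scores near zero at any window size;
#' distance-dependent data scores far above it.
#'
#' @param rel a `ddsbm_relation` (binary).
#' @param geometry a `ddsbm_geometry`.
#' @param labels true (or inferred) type assignment.
#' @param n_bins number of equal-width distance bins.
#' @param min_pairs minimum observed pairs for a bin frequency to count.
#' @return scalar variance statistic.
#' @export
connectivity_distance_variance <- function(rel, geometry, labels, n_bins = 6,
                                           min_pairs = 5) {
  keep <- rel$mask
  diag(keep) <- FALSE
  if (!rel$directed) keep <- keep & upper.tri(keep)
  idx <- which(keep, arr.ind = TRUE)
  d <- geometry$dmat[keep]
  obs <- as.numeric(rel$matrix[keep] > 0)
  br <- seq(min(d), max(d), length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(d, br, rightmost.closed = TRUE), 1), n_bins)
  tp <- paste(pmin(labels[idx[, 1]], labels[idx[, 2]]),
              pmax(labels[idx[, 1]], labels[idx[, 2]]))
  vars <- c()
  for (g in unique(tp)) {
    sel <- tp == g
    freqs <- counts <- c()
    for (b in seq_len(n_bins)) {
      s2 <- sel & bin == b
      if (sum(s2) >= min_pairs) {
        freqs <- c(freqs, mean(obs[s2]))
        counts <- c(counts, sum(s2))
      }
    }
    if (length(freqs) >= 2) {
      noise <- mean(freqs * (1 - freqs) / (counts - 1))
      vars <- c(vars, stats::var(freqs) - noise)
    }
  }
  if (length(vars) == 0) stop("fewer than 2 occupied distance bins")
  mean(vars)
}
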