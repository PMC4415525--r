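#' Cross-validation fold masks over observable pairs
#'
#' Partitions the off-diagonal observable pairs of a relation into `k`
#' disjoint folds of near-equal size. Fold j's mask marks its pairs
#' unobserved (held out); the union of held-out sets covers every
#' observable pair exactly once. Undirected relations hold out unordered
#' pairs (both mirror entries masked together); directed relations hold
#' out ordered pairs.
#'
#' @param rel a `ddsbm_relation`.
#' @param k number of folds, at least 2.
#' @return list of `k` logical mask matrices (`TRUE` = observed during
#'   training).
#' @export
make_cv_folds <- function(rel, k = 10) {
  n <- nrow(rel$matrix)
  cand <- rel$mask
  diag(cand) <- FALSE
  if (!rel$directed) cand <- cand & upper.tri(cand)
  pairs <- which(cand)
  if (length(pairs) < k) stop("fewer observable pairs than folds")
  fold_of <- sample(rep_len(seq_len(k), length(pairs)))
  lapply(seq_len(k), function(j) {
    m <- rel$mask
    held <- pairs[fold_of == j]
    m[held] <- FALSE
    if (!rel$directed) {
      mt <- t(m)
      m <- m & mt
    }
    m
  })
}

# Connection probability for the ordered pair (i, j) under one state.
# Poisson relations report P(count >= 1) = 1 - exp(-rate).
state_link_prob <- function(state, data, i, j, q = 1) {
  rel <- data$relations[[q]]
  spec <- data$hyper[[q]]
  vals <- hyper_values(spec, state$hyper_idx[[q]])
  comp <- state$comps[[q]]
  m <- state$labels[i]; n <- state$labels[j]
  d <- data$geometry$dmat[i, j]
  switch(spec$kind,
    bernoulli = logistic_bernoulli_prob(d, comp$mu[m, n], comp$lambda[m, n],
                                        vals$pmax, vals$pmin),
    poisson = 1 - exp(-logistic_poisson_rate(d, comp$mu[m, n], comp$rate[m, n],
                                             vals$lambda, vals$rate_min)),
    bernoulli_pp = percomp_pmax_bernoulli_prob(d, comp$mu[m, n], comp$p[m, n],
                                               vals$lambda, vals$pmin))
}

#' Posterior-averaged link probability
#'
#' The probability of a link between a pair of entities, averaged over the
#' full collection of posterior samples: each sample contributes the
#' connection probability implied by its assignment and parameters at the
#' pair's distance.
#'
#' @param samples a `ddsbm_samples`.
#' @param pair integer vector `c(i, j)`.
#' @param data the `ddsbm_data`.
#' @param q relation index.
#' @return probability in `[0, 1]`.
#' @export
predictive_link_prob <- function(samples, pair, data, q = 1) {
  if (length(samples$samples) == 0) stop("empty sample set")
  mean(vapply(samples$samples, state_link_prob, numeric(1),
              data = data, i = pair[1], j = pair[2], q = q))
}

#' ROC curve points
#'
#' Standard threshold sweep over unique scores, ties grouped; returns the
#' (false positive rate, true positive rate) staircase from (0,0) to
#' (1,1).
#'
#' @param scores numeric scores, higher = more likely positive.
#' @param labels 0/1 truth labels; both classes must be present.
#' @return two-column matrix with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  if (length(unique(labels)) < 2) stop("both classes must be present")
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l)
  fp <- cumsum(1 - l)
  last <- !duplicated(grp, fromLast = TRUE)
  cbind(fpr = c(0, fp[last] / nn), tpr = c(0, tp[last] / np))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a uniformly random
#' positive outscores a uniformly random negative, with ties counted half.
#' 1.0 means presence and absence are perfectly separated; constant scores
#' give 0.5.
#'
#' @inheritParams roc_points
#' @return scalar in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  if (length(unique(labels)) < 2) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Cross-validated link prediction
#'
#' For each fold, refits the model on the relation with that fold's pairs
#' masked out, scores the held-out pairs with the posterior-averaged link
#' probability, and computes the AUC against the true presence/absence.
#' Reports per-fold AUCs and the pooled AUC over all folds' held-out
#' scores concatenated before a single ROC.
#'
#' @param data a `ddsbm_data` (prediction runs on relation `q`).
#' @param config a `ddsbm_config`.
#' @param k number of folds.
#' @param q relation index.
#' @param seed seed controlling fold assignment and chain seeds.
#' @return list with `fold_auc`, `pooled_auc`, `scores`, `labels`.
#' @export
cross_validated_auc <- function(data, config, k = 10, q = 1,
                                seed = config$seed) {
  rel <- data$relations[[q]]
  set.seed(seed)
  folds <- make_cv_folds(rel, k)
  all_scores <- numeric(0)
  all_labels <- numeric(0)
  fold_auc <- numeric(k)
  for (j in seq_len(k)) {
    d2 <- data
    d2$relations[[q]]$mask <- folds[[j]]
    ss <- run_chains(d2, config, seed = seed + 100000L * j)
    held <- rel$mask & !folds[[j]]
    diag(held) <- FALSE
    if (!rel$directed) held <- held & upper.tri(held)
    idx <- which(held, arr.ind = TRUE)
    sc <- vapply(seq_len(nrow(idx)), function(r)
      predictive_link_prob(ss, c(idx[r, 1], idx[r, 2]), d2, q), numeric(1))
    lb <- as.numeric(rel$matrix[held] > 0)
    fold_auc[j] <- if (length(unique(lb)) > 1) auc(sc, lb) else NA_real_
    all_scores <- c(all_scores, sc)
    all_labels <- c(all_labels, lb)
  }
  list(fold_auc = fold_auc, pooled_auc = auc(all_scores, all_labels),
       scores = all_scores, labels = all_labels)
}

#' Posterior coassignment matrix
#'
#' Entry (i, j) is the fraction of posterior samples in which entities i
#' and j share a type: the model's confidence that they are the same cell
#' type. Symmetric with unit diagonal.
#'
#' @param samples a `ddsbm_samples`.
#' @return N x N matrix in `[0, 1]`.
#' @export
coassignment_matrix <- function(samples) {
  if (length(samples$samples) == 0) stop("empty sample set")
  n <- length(samples$samples[[1]]$labels)
  acc <- matrix(0, n, n)
  for (s in samples$samples) {
    acc <- acc + outer(s$labels, s$labels, "==")
  }
  acc / length(samples$samples)
}

#' Deterministic block-sorting permutation of a coassignment matrix
#'
#' Orders entities so that high-coassignment groups are contiguous, via
#' average-linkage agglomerative clustering of the dissimilarity
#' `1 - coassignment`. The same input always yields the same permutation.
#'
#' @param coassign symmetric matrix in `[0, 1]`.
#' @return integer permutation of `1..N`.
#' @export
sort_for_blocks <- function(coassign) {
  if (!isTRUE(all.equal(coassign, t(coassign))))
    stop("coassignment matrix must be symmetric")
  d <- stats::as.dist(1 - coassign)
  stats::hclust(d, method = "average")$order
}
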