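#' Construct a connectivity relation
#'
#' A relation is one observed graph over N entities: a square matrix of
#' observations, an observation model, a directedness flag, and an
#' observation mask. Masked-out entries (mask = `FALSE`) are treated as
#' unobserved and contribute nothing to any likelihood; they are the
#' held-out pairs in link-prediction experiments.
#'
#' @param matrix N x N numeric matrix. Binary `{0,1}` for `kind =
#'   "bernoulli"` and `"bernoulli_pp"`; nonnegative integer counts for
#'   `kind = "poisson"`.
#' @param kind observation model: `"bernoulli"` (logistic-distance
#'   Bernoulli), `"poisson"` (logistic-distance Poisson), or
#'   `"bernoulli_pp"` (Bernoulli with a per-component probability ceiling).
#' @param directed logical; undirected relations must have symmetric
#'   `matrix` and `mask`, and their likelihood iterates unordered pairs.
#' @param mask optional N x N logical matrix, `TRUE` = observed. Defaults
#'   to all observed.
#' @return an object of class `ddsbm_relation`.
#' @export
relation <- function(matrix, kind = c("bernoulli", "poisson", "bernoulli_pp"),
                     directed = FALSE, mask = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("relation matrix must be square")
  storage.mode(matrix) <- "double"
  if (is.null(mask)) mask <- base::matrix(TRUE, nrow(matrix), ncol(matrix))
  if (!identical(dim(mask), dim(matrix)))
    stop("mask shape must equal matrix shape")
  rel <- structure(list(matrix = matrix, kind = kind,
                        directed = isTRUE(directed), mask = mask),
                   class = "ddsbm_relation")
  bad <- validate_relation(rel)
  if (length(bad)) stop("invalid relation: ", paste(bad, collapse = "; "))
  rel
}

validate_relation <- function(rel) {
  v <- character()
  m <- rel$matrix
  if (rel$kind %in% c("bernoulli", "bernoulli_pp")) {
    if (!all(m %in% c(0, 1))) v <- c(v, "bernoulli entries must be in {0,1}")
  } else {
    if (any(m < 0) || any(m != round(m)))
      v <- c(v, "poisson entries must be nonnegative integers")
  }
  if (!rel$directed) {
    if (!isTRUE(all.equal(m, t(m)))) v <- c(v, "undirected matrix must be symmetric")
    if (!identical(rel$mask, t(rel$mask))) v <- c(v, "undirected mask must be symmetric")
  }
  v
}

#' Entity geometry: coordinates and pairwise distances
#'
#' @param positions N x D numeric matrix of coordinates (D in 1..3), in the
#'   units of the source data (micrometres, or normalized body axis).
#' @param dmat optional precomputed N x N distance matrix; defaults to
#'   Euclidean distances between rows of `positions`. Must be symmetric,
#'   nonnegative, with zero diagonal.
#' @return an object of class `ddsbm_geometry` with elements `positions`
#'   and `dmat`.
#' @export
entity_geometry <- function(positions = NULL, dmat = NULL) {
  if (is.null(dmat)) {
    if (is.null(positions)) stop("supply positions or dmat")
    positions <- as.matrix(positions)
    dmat <- as.matrix(stats::dist(positions))
  } else {
    dmat <- as.matrix(dmat)
  }
  if (any(dmat < 0) || any(diag(dmat) != 0) || !isTRUE(all.equal(dmat, t(dmat))))
    stop("distance matrix must be symmetric, nonnegative, zero on the diagonal")
  structure(list(positions = positions, dmat = unname(dmat)),
            class = "ddsbm_geometry")
}

#' Replace geometry by a distance-blind (constant-distance) version
#'
#' Used for the plain-iSBM ablation: with all pairwise distances equal, the
#' logistic link collapses to a free per-component connection probability,
#' so the model reduces to an infinite stochastic block model that ignores
#' space.
#'
#' @param geometry a `ddsbm_geometry`.
#' @param value constant off-diagonal distance; defaults to the mean
#'   observed pairwise distance.
#' @return a `ddsbm_geometry` with constant off-diagonal distances.
#' @export
distance_blind <- function(geometry, value = NULL) {
  d <- geometry$dmat
  if (is.null(value)) value <- mean(d[upper.tri(d)])
  d[] <- value
  diag(d) <- 0
  entity_geometry(positions = geometry$positions, dmat = d)
}

#' Bundle relations, geometry, features and priors into a model dataset
#'
#' @param relations a `ddsbm_relation` or list of them (all over the same
#'   entities); multiple relations share one clustering and multiply their
#'   likelihoods.
#' @param geometry a `ddsbm_geometry` over the same entities.
#' @param hyper a `ddsbm_hyperspec` per relation (see [hyper_spec()]);
#'   defaults are built from each relation's kind.
#' @param soma_depth optional length-N numeric vector of normalized soma
#'   depths in `[0,1]` (`NA` = missing, contributes nothing).
#' @param synapse_depths optional length-N list of numeric vectors of
#'   normalized synapse depths per entity.
#' @param alpha_grid candidate values for the CRP concentration.
#' @param soma_hyper hyperparameters of the conjugate
#'   Normal/scaled-inverse-chi-squared soma-depth model:
#'   `c(mu0, kappa0, sigma02, nu0)`.
#' @param profile_m number of synapse-profile mixture components (at most 3).
#' @param profile_sigma2_grid candidate global variance scales of the
#'   synapse profile mixture, in squared normalized-depth units.
#' @return an object of class `ddsbm_data`.
#' @export
ddsbm_data <- function(relations, geometry, hyper = NULL,
                       soma_depth = NULL, synapse_depths = NULL,
                       alpha_grid = c(0.1, 0.3, 1, 3, 10),
                       soma_hyper = c(mu0 = 0.5, kappa0 = 1, sigma02 = 0.04, nu0 = 2),
                       profile_m = 3,
                       profile_sigma2_grid = c(0.01, 0.1, 1.0)) {
  if (inherits(relations, "ddsbm_relation")) relations <- list(relations)
  n <- nrow(relations[[1]]$matrix)
  for (r in relations) {
    stopifnot(inherits(r, "ddsbm_relation"))
    if (nrow(r$matrix) != n) stop("all relations must cover the same entities")
  }
  if (nrow(geometry$dmat) != n) stop("geometry dimension mismatch")
  if (is.null(hyper)) hyper <- lapply(relations, function(r) hyper_spec(r$kind))
  if (inherits(hyper, "ddsbm_hyperspec")) hyper <- list(hyper)
  if (length(hyper) != length(relations)) stop("one hyper spec per relation")
  if (!is.null(soma_depth) && length(soma_depth) != n) stop("soma_depth length mismatch")
  if (!is.null(synapse_depths) && length(synapse_depths) != n)
    stop("synapse_depths length mismatch")
  if (profile_m > 3) stop("synapse profile supports at most 3 mixture components")
  structure(list(relations = relations, geometry = geometry, hyper = hyper,
                 soma_depth = soma_depth, synapse_depths = synapse_depths,
                 alpha_grid = alpha_grid, soma_hyper = soma_hyper,
                 profile_m = profile_m,
                 profile_sigma2_grid = profile_sigma2_grid,
                 n = n),
            class = "ddsbm_data")
}

n_entities <- function(data) data$n

#' Validate a model state
#'
#' Checks the structural invariants of a model state: contiguous
#' type labels `1..K` with every type non-empty, component-parameter tables
#' tracking K for every relation, parameters within their domains, in-range
#' hyperparameter grid indices, and temperature at least 1. Reports
#' violations rather than raising.
#'
#' @param state a `ddsbm_state`.
#' @param data the `ddsbm_data` the state belongs to.
#' @return character vector of violations; empty if the state is valid.
#' @export
validate_state <- function(state, data) {
  v <- character()
  lab <- state$labels
  K <- state$K
  if (length(lab) != data$n) v <- c(v, "label vector length mismatch")
  if (any(lab < 1) || any(lab > K)) v <- c(v, "labels outside 1..K")
  sz <- tabulate(lab, K)
  for (k in which(sz == 0)) v <- c(v, sprintf("type %d is empty", k))
  if (!(is.numeric(state$temperature) && state$temperature >= 1))
    v <- c(v, "temperature must be >= 1")
  for (q in seq_along(data$relations)) {
    comp <- state$comps[[q]]
    spec <- data$hyper[[q]]
    for (nm in names(comp)) {
      if (!identical(dim(comp[[nm]]), c(K, K)))
        v <- c(v, sprintf("relation %d: %s table is not K x K", q, nm))
    }
    if (spec$kind %in% c("bernoulli", "poisson")) {
      if (any(comp$mu <= 0)) v <- c(v, sprintf("relation %d: mu must be > 0", q))
      p2 <- if (spec$kind == "bernoulli") comp$lambda else comp$rate
      if (any(p2 <= 0)) v <- c(v, sprintf("relation %d: scale/rate must be > 0", q))
    } else {
      if (any(comp$p <= 0 | comp$p >= 1))
        v <- c(v, sprintf("relation %d: p must lie in (0,1)", q))
      if (any(comp$mu <= 0)) v <- c(v, sprintf("relation %d: mu must be > 0", q))
    }
    idx <- state$hyper_idx[[q]]
    sizes <- grid_sizes(spec)
    if (length(idx) != length(sizes) || any(idx < 1) || any(idx > sizes))
      v <- c(v, sprintf("relation %d: hyper index out of range", q))
  }
  if (state$alpha_idx < 1 || state$alpha_idx > length(data$alpha_grid))
    v <- c(v, "alpha index out of range")
  v
}

#' Canonicalize type labels to contiguous 1..K
#'
#' Relabels types in order of first appearance so that empty types never
#' persist; used after every kernel sweep.
#'
#' @param labels integer vector of type indices.
#' @return list with `labels` (relabeled), `K`, and `map` such that
#'   `new = map[old]` (`NA` for types that were empty).
#' @export
canonicalize_labels <- function(labels) {
  u <- unique(labels)
  map <- rep(NA_integer_, max(labels))
  map[u] <- seq_along(u)
  list(labels = map[labels], K = length(u), map = map)
}

#' @export
print.ddsbm_relation <- function(x, ...) {
  cat(sprintf("<ddsbm_relation> %d x %d, %s, %s, %d/%d pairs observed\n",
              nrow(x$matrix), ncol(x$matrix), x$kind,
              if (x$directed) "directed" else "undirected",
              sum(x$mask) - sum(diag(x$mask)), length(x$mask) - nrow(x$matrix)))
  invisible(x)
}

#' @export
print.ddsbm_data <- function(x, ...) {
  cat(sprintf("<ddsbm_data> %d entities, %d relation(s)%s%s\n", x$n,
              length(x$relations),
              if (!is.null(x$soma_depth)) ", soma depths" else "",
              if (!is.null(x$synapse_depths)) ", synapse profiles" else ""))
  invisible(x)
}
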