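#' Adjusted Rand index
#'
#' Chance-corrected agreement of two partitions, computed from the
#' contingency table: `(Index - E[Index]) / (MaxIndex - E[Index])`.
#' Identical partitions (up to label permutation) score 1.0; independent
#' random partitions score 0 in expectation; anti-correlated partitions
#' can be slightly negative.
#'
#' @param a,b label vectors of equal length.
#' @return scalar, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (mx - expected)
}

entropy_nats <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

cond_entropy <- function(target, given) {
  tab <- table(given, target)
  n <- sum(tab)
  h <- 0
  for (r in seq_len(nrow(tab))) {
    row <- tab[r, ]
    if (sum(row) > 0) h <- h + sum(row) / n * entropy_nats(row)
  }
  h
}

#' Clustering homogeneity
#'
#' `1 - H(truth | found) / H(truth)`: the degree to which each found type
#' contains only a single true type. Splitting a true type leaves
#' homogeneity at 1 (each subtype is still pure); merging two true types
#' lowers it. Defined as 1 when `H(truth)` is 0.
#'
#' @param truth,found label vectors of equal length.
#' @return scalar in `[0, 1]`.
#' @export
homogeneity <- function(truth, found) {
  if (length(truth) != length(found)) stop("label vectors must have equal length")
  h <- entropy_nats(table(truth))
  if (h == 0) return(1)
  1 - cond_entropy(truth, found) / h
}

#' Clustering completeness
#'
#' `1 - H(found | truth) / H(found)`: how much of each true type lands in
#' a single found type. Merging true types leaves completeness at 1;
#' splitting a true type lowers it. Defined as 1 when `H(found)` is 0.
#'
#' @inheritParams homogeneity
#' @return scalar in `[0, 1]`.
#' @export
completeness <- function(truth, found) {
  if (length(truth) != length(found)) stop("label vectors must have equal length")
  h <- entropy_nats(table(found))
  if (h == 0) return(1)
  1 - cond_entropy(found, truth) / h
}

#' Distribute one type's members among the remaining types
#'
#' Perturbation used to probe the agreement metrics: every member of
#' `type_id` is reassigned independently and uniformly over the other
#' types, and the type disappears (K decreases by 1). Detrimental to all
#' three metrics.
#'
#' @param a label vector with at least 2 types.
#' @param type_id type to dissolve.
#' @return relabeled vector with contiguous labels.
#' @export
perturb_distribute <- function(a, type_id) {
  types <- sort(unique(a))
  if (length(types) < 2) stop("need at least 2 types to distribute one")
  if (!type_id %in% types) stop("no such type")
  others <- setdiff(types, type_id)
  idx <- which(a == type_id)
  a[idx] <- others[sample.int(length(others), length(idx), replace = TRUE)]
  canonicalize_labels(a)$labels
}

#' Merge one type into another
#'
#' Members of `type_a` are relabeled `type_b`; K decreases by 1. Merging
#' leaves completeness against the original labels at 1 but lowers
#' homogeneity.
#'
#' @param a label vector.
#' @param type_a,type_b distinct existing types.
#' @return relabeled vector with contiguous labels.
#' @export
perturb_merge <- function(a, type_a, type_b) {
  if (type_a == type_b) stop("types to merge must be distinct")
  if (!all(c(type_a, type_b) %in% a)) stop("no such type")
  a[a == type_a] <- type_b
  canonicalize_labels(a)$labels
}

#' Split one type into two
#'
#' Members of `type_id` are randomly bisected into two new types; K
#' increases by 1. Splitting leaves homogeneity against the original
#' labels at 1 but lowers completeness.
#'
#' @param a label vector.
#' @param type_id type with at least 2 members.
#' @return relabeled vector with contiguous labels.
#' @export
perturb_split <- function(a, type_id) {
  idx <- which(a == type_id)
  if (length(idx) < 2) stop("cannot split a singleton type")
  new_type <- max(a) + 1L
  half <- sample(idx, floor(length(idx) / 2))
  a[half] <- new_type
  canonicalize_labels(a)$labels
}

#' Spatial extent of each type
#'
#' Root-mean-square deviation of member coordinates from the type
#' centroid, per type, in the (lateral) plane of the supplied positions.
#' A type uniform on a disc of radius R has extent `R / sqrt(2)`;
#' singleton types have extent 0.
#'
#' @param labels type assignment.
#' @param geometry a `ddsbm_geometry` with positions.
#' @param dims which coordinate columns form the lateral plane (default:
#'   all).
#' @return named numeric vector of per-type extents, in position units.
#' @export
spatial_extent <- function(labels, geometry, dims = NULL) {
  pos <- geometry$positions
  if (is.null(pos)) stop("geometry has no positions")
  if (is.null(dims)) dims <- seq_len(ncol(pos))
  vapply(sort(unique(labels)), function(k) {
    p <- pos[labels == k, dims, drop = FALSE]
    ctr <- colMeans(p)
    sqrt(mean(rowSums(sweep(p, 2, ctr)^2)))
  }, numeric(1))
}
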