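#' Load a contact-area matrix as a binary relation
#'
#' Serial-EM reconstructions report the total synapse-like contact area
#' between every pair of cells. Entries strictly above the threshold
#' (default 0.1, in square micrometres) become edges; distances are
#' Euclidean between reconstructed soma centers. The resulting relation is
#' undirected (contact area is symmetric in nature).
#'
#' @param area N x N nonnegative symmetric matrix of contact areas.
#' @param soma_positions N x D matrix of soma-center coordinates.
#' @param threshold area threshold; strictly greater-than comparison.
#' @return list with `relation` (bernoulli, undirected) and `geometry`.
#' @export
load_contact_area <- function(area, soma_positions, threshold = 0.1) {
  area <- as.matrix(area)
  if (any(area < 0)) stop("contact areas must be nonnegative")
  if (nrow(area) != ncol(area)) stop("area matrix must be square")
  A <- (area > threshold) * 1
  A[lower.tri(A)] <- t(A)[lower.tri(A)]  # symmetrize against asymmetric input
  list(relation = relation(A, kind = "bernoulli", directed = FALSE),
       geometry = entity_geometry(as.matrix(soma_positions)))
}

#' Load paired chemical/electrical synapse-count graphs
#'
#' Counts are divided by `scale` (default 4.0, compensating for Poisson
#' overdispersion in raw synapse counts) and rounded half-up to integers.
#' The chemical graph is kept directed; the electrical graph is
#' symmetrized by maximum. Positions are distances along the
#' anterior-posterior body axis, normalized to `[0, 1]`.
#'
#' @param chemical N x N nonnegative count matrix (directed).
#' @param electrical N x N nonnegative count matrix (undirected).
#' @param positions length-N numeric vector in `[0, 1]`.
#' @param scale count divisor.
#' @return list with `relations` (list of two poisson relations: chemical
#'   then electrical) and `geometry`.
#' @export
load_two_graph_counts <- function(chemical, electrical, positions,
                                  scale = 4.0) {
  if (any(chemical < 0) || any(electrical < 0)) stop("counts must be nonnegative")
  if (any(positions < 0 | positions > 1))
    stop("positions must lie in [0, 1]")
  round_half_up <- function(x) floor(x + 0.5)
  chem <- round_half_up(as.matrix(chemical) / scale)
  elec <- round_half_up(as.matrix(electrical) / scale)
  elec <- pmax(elec, t(elec))
  diag(chem) <- 0; diag(elec) <- 0
  list(relations = list(
         chemical = relation(chem, kind = "poisson", directed = TRUE),
         electrical = relation(elec, kind = "poisson", directed = FALSE)),
       geometry = entity_geometry(matrix(positions, ncol = 1)))
}

#' Load a transistor netlist as six terminal-pairing relations
#'
#' Each transistor has terminals g (gate), c1, and c2 (source/drain,
#' unresolved). For each of the six distinct terminal pairings
#' (g-g, g-c1, g-c2, c1-c1, c1-c2, c2-c2), transistors i and j are
#' connected iff some wire joins the first terminal of i to the second
#' terminal of j. Same-terminal pairings yield symmetric relations;
#' mixed pairings are symmetrized (a g-c1 wire between i and j is the
#' same physical junction seen from either side), so all six relations
#' are undirected.
#'
#' @param terminals data frame with columns `transistor`, `terminal`
#'   (one of `"g"`, `"c1"`, `"c2"`), `net` (wire id); every transistor
#'   must list all three terminals.
#' @param coords N x 2 matrix of transistor coordinates, rows in
#'   transistor order.
#' @return list with `relations` (named list of 6 bernoulli relations)
#'   and `geometry`.
#' @export
load_transistor_netlist <- function(terminals, coords) {
  ids <- sort(unique(terminals$transistor))
  n <- length(ids)
  need <- c("g", "c1", "c2")
  for (id in ids) {
    have <- terminals$terminal[terminals$transistor == id]
    if (!all(need %in% have))
      stop("transistor ", id, " is missing a terminal")
  }
  net_of <- function(term) {
    v <- rep(NA_character_, n)
    sel <- terminals$terminal == term
    v[match(terminals$transistor[sel], ids)] <- as.character(terminals$net[sel])
    v
  }
  nets <- lapply(stats::setNames(need, need), net_of)
  pairings <- list(gg = c("g", "g"), gc1 = c("g", "c1"), gc2 = c("g", "c2"),
                   c1c1 = c("c1", "c1"), c1c2 = c("c1", "c2"),
                   c2c2 = c("c2", "c2"))
  rels <- lapply(pairings, function(pr) {
    A <- outer(nets[[pr[1]]], nets[[pr[2]]], "==") * 1
    A[is.na(A)] <- 0
    A <- pmax(A, t(A))
    diag(A) <- 0
    relation(A, kind = "bernoulli", directed = FALSE)
  })
  list(relations = rels, geometry = entity_geometry(as.matrix(coords)))
}
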