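#' Read a relation from a file
#'
#' Supported formats: `dense_csv` (square numeric matrix, optional header
#' ignored), `sparse_triplet` (CSV with columns `i`, `j`, `value`,
#' 1-based; absent entries are 0; `n` gives the matrix size), and
#' `matrix_market` (via [Matrix::readMM]).
#'
#' @param path file path.
#' @param format one of `"dense_csv"`, `"sparse_triplet"`,
#'   `"matrix_market"`.
#' @param kind,directed passed to [relation()].
#' @param n matrix dimension, required for `sparse_triplet`.
#' @return a `ddsbm_relation`.
#' @export
read_relation <- function(path, format = c("dense_csv", "sparse_triplet",
                                           "matrix_market"),
                          kind = "bernoulli", directed = FALSE, n = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  m <- switch(format,
    dense_csv = {
      rows <- utils::read.csv(path, header = FALSE,
                              colClasses = "numeric")
      mm <- as.matrix(rows)
      if (nrow(mm) != ncol(mm))
        stop(sprintf("%s: dense matrix is %d x %d, not square",
                     path, nrow(mm), ncol(mm)))
      mm
    },
    sparse_triplet = {
      tr <- utils::read.csv(path)
      if (!all(c("i", "j", "value") %in% names(tr)))
        stop(path, ": triplet file needs columns i, j, value")
      if (is.null(n)) n <- max(tr$i, tr$j)
      mm <- matrix(0, n, n)
      mm[cbind(tr$i, tr$j)] <- tr$value
      mm
    },
    matrix_market = as.matrix(Matrix::readMM(path)))
  dimnames(m) <- NULL
  relation(m, kind = kind, directed = directed)
}

#' Read entity positions from a tabular file
#'
#' CSV with an `id` column plus coordinate columns; rows are joined to
#' `ids` (or sorted by id when `ids` is `NULL`), so file row order does
#' not matter. Duplicate ids are an error.
#'
#' @param path CSV path.
#' @param ids optional id ordering to match the relation's entities.
#' @return a `ddsbm_geometry`.
#' @export
read_positions <- function(path, ids = NULL) {
  df <- utils::read.csv(path)
  if (!"id" %in% names(df)) stop("positions file needs an id column")
  if (anyDuplicated(df$id)) stop("duplicate entity id in positions file")
  if (is.null(ids)) ids <- sort(df$id)
  if (!setequal(ids, df$id)) stop("position ids do not match entity ids")
  df <- df[match(ids, df$id), , drop = FALSE]
  m <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  dimnames(m) <- NULL
  entity_geometry(m)
}

#' Read feature data (soma depths and synapse depths)
#'
#' `soma_path`: CSV with columns `id`, `depth`. `synapse_path`: long CSV
#' with columns `id`, `depth`, one row per synapse; entities without rows
#' get empty synapse lists.
#'
#' @param soma_path,synapse_path CSV paths (either may be `NULL`).
#' @param ids entity id ordering.
#' @return list with `soma_depth` and `synapse_depths`.
#' @export
read_features <- function(soma_path = NULL, synapse_path = NULL, ids) {
  soma <- NULL
  syn <- NULL
  if (!is.null(soma_path)) {
    df <- utils::read.csv(soma_path)
    if (anyDuplicated(df$id)) stop("duplicate entity id in soma file")
    soma <- df$depth[match(ids, df$id)]
  }
  if (!is.null(synapse_path)) {
    df <- utils::read.csv(synapse_path)
    syn <- lapply(ids, function(i) df$depth[df$id == i])
  }
  list(soma_depth = soma, synapse_depths = syn)
}

state_to_list <- function(state) {
  list(labels = state$labels, K = state$K,
       comps = lapply(state$comps, function(cc) lapply(cc, function(M)
         list(dim = dim(M), values = as.numeric(M)))),
       hyper_idx = lapply(state$hyper_idx, as.list),
       alpha_idx = state$alpha_idx,
       profile = if (is.null(state$profile)) NULL else list(
         means = list(dim = dim(state$profile$means),
                      values = as.numeric(state$profile$means)),
         weights = list(dim = dim(state$profile$weights),
                        values = as.numeric(state$profile$weights)),
         sigma2_idx = state$profile$sigma2_idx),
       temperature = state$temperature)
}

list_to_state <- function(x) {
  restore <- function(m) {
    dm <- as.integer(unlist(m$dim))
    matrix(as.numeric(unlist(m$values)), dm[1], dm[2])
  }
  structure(list(
    labels = as.integer(unlist(x$labels)), K = as.integer(x$K),
    comps = lapply(x$comps, function(cc) lapply(cc, restore)),
    hyper_idx = lapply(x$hyper_idx, function(h)
      vapply(h, as.integer, integer(1))),
    alpha_idx = as.integer(x$alpha_idx),
    profile = if (is.null(x$profile) || length(x$profile) == 0) NULL else list(
      means = restore(x$profile$means),
      weights = restore(x$profile$weights),
      sigma2_idx = as.integer(x$profile$sigma2_idx)),
    temperature = as.numeric(x$temperature)), class = "ddsbm_state")
}

RESULTS_SCHEMA_VERSION <- 1L

#' Write a results archive
#'
#' Stores all posterior samples, their log scores, per-chain traces, and
#' the configuration as versioned JSON plus CSV traces in a directory.
#' Reloading with [read_results()] reproduces identical downstream
#' metrics.
#'
#' @param samples a `ddsbm_samples`.
#' @param path directory to create.
#' @param config optional `ddsbm_config` to record.
#' @return `path`, invisibly.
#' @export
write_results <- function(samples, path, config = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  payload <- list(schema_version = RESULTS_SCHEMA_VERSION,
                  states = lapply(samples$samples, state_to_list),
                  log_scores = samples$log_scores,
                  chain_ids = samples$chain_ids,
                  config = if (is.null(config)) NULL else unclass(config))
  jsonlite::write_json(payload, file.path(path, "samples.json"),
                       auto_unbox = TRUE, digits = NA)
  tr <- do.call(cbind, samples$traces)
  colnames(tr) <- paste0("chain", samples$chain_ids)
  utils::write.csv(tr, file.path(path, "traces.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a results archive
#'
#' @param path directory written by [write_results()].
#' @return a `ddsbm_samples`.
#' @export
read_results <- function(path) {
  payload <- jsonlite::read_json(file.path(path, "samples.json"))
  if (!identical(as.integer(payload$schema_version), RESULTS_SCHEMA_VERSION))
    stop("unsupported results schema version: ", payload$schema_version)
  tr <- utils::read.csv(file.path(path, "traces.csv"))
  structure(list(samples = lapply(payload$states, list_to_state),
                 log_scores = vapply(payload$log_scores, as.numeric,
                                     numeric(1)),
                 chain_ids = vapply(payload$chain_ids, as.integer, integer(1)),
                 traces = lapply(seq_len(ncol(tr)), function(j) tr[[j]])),
            class = "ddsbm_samples")
}

#' Write a relation to dense CSV
#'
#' @param rel a `ddsbm_relation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_relation <- function(rel, path) {
  utils::write.table(rel$matrix, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write entity positions to CSV
#'
#' @param geometry a `ddsbm_geometry` with positions.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_positions <- function(geometry, path) {
  pos <- geometry$positions
  df <- data.frame(id = seq_len(nrow(pos)))
  for (j in seq_len(ncol(pos))) df[[paste0("x", j)]] <- pos[, j]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
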