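#' Regional BOLD time-series matrix
#'
#' Container for parcellated fMRI signals: one row per brain region, one
#' column per scan volume. The values are BOLD signal in arbitrary scanner
#' units; only their correlation structure matters downstream.
#'
#' @param values Numeric matrix, regions x time points.
#' @param region_labels Character vector of region identifiers, one per row.
#'   Defaults to `"R1".."Rn"`.
#' @param sampling_interval Seconds between successive volumes (the scanner
#'   repetition time). Default 1.5 s.
#' @return A `bold_matrix` object (a numeric matrix with metadata attributes).
#' @export
bold_matrix <- function(values, region_labels = NULL, sampling_interval = 1.5) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values))) {
    stop_input("BOLD values must be a finite numeric matrix")
  }
  if (nrow(values) < 2) stop_input("a BOLD matrix needs at least 2 regions")
  if (ncol(values) < 3) stop_input("a BOLD matrix needs at least 3 time points")
  assert_scalar_number(sampling_interval, "sampling_interval", lower = 1e-9)
  region_labels <- region_labels %||% paste0("R", seq_len(nrow(values)))
  if (length(region_labels) != nrow(values)) {
    stop_input("need exactly one label per region")
  }
  rownames(values) <- region_labels
  structure(values,
            sampling_interval = sampling_interval,
            class = c("bold_matrix", "matrix", "array"))
}

#' Undirected binary graph used as a reservoir wiring scaffold
#'
#' @param n_nodes Number of nodes.
#' @param edges Two-column integer matrix of unordered node pairs (1-based).
#' @param meta Named list of provenance fields (generator, parameters,
#'   threshold, seed).
#' @return A `topology` object.
#' @export
topology <- function(n_nodes, edges, meta = list()) {
  n_nodes <- as.integer(n_nodes)
  if (is.null(dim(edges))) edges <- matrix(as.integer(edges), ncol = 2)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 1L) || any(edges > n_nodes)) {
      stop_input("edge endpoints must be node indices in [1, n_nodes]")
    }
    if (any(edges[, 1] == edges[, 2])) stop_input("self-loops are not allowed")
    edges <- t(apply(edges, 1, sort))
    key <- paste(edges[, 1], edges[, 2])
    if (anyDuplicated(key)) stop_input("duplicate edges are not allowed")
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  structure(list(n_nodes = n_nodes, edges = edges, meta = meta),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d nodes, %d edges", x$n_nodes, nrow(x$edges)))
  if (!is.null(x$meta$generator)) cat(sprintf(" [%s]", x$meta$generator))
  cat("\n")
  invisible(x)
}

#' Convert a topology to an igraph graph
#' @param top A [topology()].
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(top) {
  stopifnot(inherits(top, "topology"))
  if (nrow(top$edges) == 0) {
    return(igraph::make_empty_graph(top$n_nodes, directed = FALSE))
  }
  g <- igraph::graph_from_edgelist(top$edges, directed = FALSE)
  if (igraph::vcount(g) < top$n_nodes) {
    g <- igraph::add_vertices(g, top$n_nodes - igraph::vcount(g))
  }
  g
}

#' Speech feature matrix (static MFCC + deltas)
#'
#' A 39 x T matrix: rows 1-13 hold the static cepstra, 14-26 the first-order
#' (delta) and 27-39 the second-order (delta-delta) dynamic features.
#'
#' @param values Numeric matrix with exactly 39 rows.
#' @param frame_step Seconds between frame centres.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, frame_step) {
  values <- as.matrix(values)
  if (nrow(values) != 39) stop_input("a feature matrix must have exactly 39 rows")
  if (ncol(values) < 1) stop_input("a feature matrix needs at least one frame")
  if (!all(is.finite(values))) stop_input("feature values must be finite")
  assert_scalar_number(frame_step, "frame_step", lower = 1e-9)
  structure(values, frame_step = frame_step,
            class = c("feature_matrix", "matrix", "array"))
}

#' Binary spike raster
#'
#' @param values Binary (0/1) matrix, channels x timesteps.
#' @param dt Seconds per timestep.
#' @return A `spike_raster` object.
#' @export
spike_raster <- function(values, dt) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (!all(values %in% c(0L, 1L))) stop_input("a spike raster must be binary")
  assert_scalar_number(dt, "dt", lower = 1e-12)
  structure(values, dt = dt, class = c("spike_raster", "matrix", "array"))
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d channels x %d steps (dt = %g s), %d spikes\n",
              nrow(x), ncol(x), attr(x, "dt"), sum(x)))
  invisible(x)
}

#' Mono audio waveform
#'
#' @param samples Numeric amplitude sequence (dimensionless, nominally in
#'   \[-1, 1\]).
#' @param sample_rate Sampling rate in Hz.
#' @return A `waveform` object.
#' @export
waveform <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop_input("waveform samples must be finite")
  assert_scalar_number(sample_rate, "sample_rate", lower = 1)
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.0f ms)\n",
              length(x$samples), x$sample_rate,
              1000 * length(x$samples) / x$sample_rate))
  invisible(x)
}
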