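#' Per-bin population firing counts
#'
#' Sums a reservoir raster over neurons within consecutive time bins. These
#' per-timepoint totals are the observations of the firing-separability
#' ANOVA: one group per stimulus class, one observation per time bin.
#'
#' @param result A `simulation_result` (or a [spike_raster()]).
#' @param bin Bin width, ms (default 1).
#' @return Numeric vector of per-bin spike totals.
#' @export
firing_counts <- function(result, bin = 1) {
  raster <- if (inherits(result, "simulation_result")) result$raster else result
  stopifnot(inherits(raster, "spike_raster"))
  dt_ms <- attr(raster, "dt") * 1000
  if (bin <= 0) stop_input("`bin` must be positive")
  if (bin > ncol(raster) * dt_ms) stop_input("`bin` exceeds the raster duration")
  spb <- max(1L, round(bin / dt_ms))
  n_bins <- ncol(raster) %/% spb
  per_step <- colSums(unclass(raster))
  colSums(matrix(per_step[seq_len(n_bins * spb)], nrow = spb))
}

#' One-way analysis of variance
#'
#' F = MS_between / MS_within with (k - 1, N - k) degrees of freedom; a larger
#' F means the group means differ more relative to the within-group scatter.
#' A zero within-group variance is flagged as degenerate rather than reported
#' as an infinite F.
#'
#' @param groups List (optionally named) of numeric samples, one per group.
#' @return An `anova_result`: list with `f_value`, `p_value`, `df_between`,
#'   `df_within`, `ss_between`, `ss_within`, `degenerate`.
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop_input("need at least 2 groups")
  }
  if (any(lengths(groups) < 2)) stop_input("every group needs >= 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ss_within <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  k <- length(groups)
  n <- length(y)
  if (ss_within == 0) {
    return(structure(list(f_value = NA_real_, p_value = NA_real_,
                          df_between = k - 1L, df_within = n - k,
                          ss_between = sum((tapply(y, g, mean)[g] - mean(y))^2),
                          ss_within = 0, degenerate = TRUE),
                     class = "anova_result"))
  }
  tab <- summary(stats::aov(y ~ g))[[1]]
  structure(list(f_value = tab$`F value`[1], p_value = tab$`Pr(>F)`[1],
                 df_between = tab$Df[1], df_within = tab$Df[2],
                 ss_between = tab$`Sum Sq`[1], ss_within = tab$`Sum Sq`[2],
                 degenerate = FALSE),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<anova_result> degenerate: zero within-group variance\n")
  } else {
    cat(sprintf("<anova_result> F(%d, %d) = %.4g, p = %.3g\n",
                x$df_between, x$df_within, x$f_value, x$p_value))
  }
  invisible(x)
}

#' Synaptic density
#'
#' Number of active synapses (non-zero weight, i.e. able to transmit firing)
#' per neuron.
#'
#' @param synapses A synapse tibble with a `g` column (e.g.
#'   `simulation_result$synapses`).
#' @param n_neurons Neuron count.
#' @return Active synapses per neuron.
#' @export
synaptic_density <- function(synapses, n_neurons) {
  if (n_neurons < 1) stop_input("`n_neurons` must be >= 1")
  sum(synapses$g > 0) / n_neurons
}

#' Weighted graph view of a synapse table
#'
#' Symmetrizes a directed synapse table into an undirected weighted graph:
#' the weight between i and j is the mean of the two directed weights. The
#' binary adjacency is derived as weight > 0.
#'
#' @param synapses A synapse tibble (`pre`, `post`, `g`).
#' @param n_neurons Node count.
#' @return A `weighted_graph_view`: list with `n`, `weights` (symmetric
#'   matrix) and `adjacency` (logical matrix).
#' @export
synapse_graph_view <- function(synapses, n_neurons) {
  w <- matrix(0, n_neurons, n_neurons)
  w[cbind(synapses$pre, synapses$post)] <- synapses$g
  weighted_graph_view((w + t(w)) / 2)
}

#' @rdname synapse_graph_view
#' @param weights Symmetric non-negative weight matrix (zero diagonal).
#' @export
weighted_graph_view <- function(weights) {
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == ncol(weights))
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop_input("weights must be finite and non-negative")
  }
  if (max(abs(weights - t(weights))) > 1e-12) {
    stop_input("weight matrix must be symmetric")
  }
  diag(weights) <- 0
  structure(list(n = nrow(weights), weights = weights,
                 adjacency = weights > 0),
            class = "weighted_graph_view")
}

#' Weighted average clustering coefficient
#'
#' Node i contributes
#' \deqn{\frac{1}{s_i (D_i - 1)} \sum_{j \ne k}
#'   \frac{g_{ij} + g_{ik}}{2}\, a_{ij} a_{jk} a_{ki},}
#' summing over ordered neighbour pairs (so that with uniform weights the
#' term reduces to the binary local clustering coefficient); nodes with
#' degree < 2 contribute 0, and C_w is the mean over nodes. High C_w means
#' strong local information transmission.
#'
#' @param g A `weighted_graph_view`.
#' @return Scalar C_w in \[0, 1\] for weights scaled like the adjacency.
#' @export
weighted_cc <- function(g) {
  stopifnot(inherits(g, "weighted_graph_view"))
  a <- g$adjacency
  w <- g$weights
  terms <- vapply(seq_len(g$n), function(i) {
    nbr <- which(a[i, ])
    d_i <- length(nbr)
    if (d_i < 2) return(0)
    s_i <- sum(w[i, ])
    tot <- 0
    for (j in nbr) for (k in nbr) {
      if (j != k && a[j, k]) tot <- tot + (w[i, j] + w[i, k]) / 2
    }
    tot / (s_i * (d_i - 1))
  }, numeric(1))
  mean(terms)
}

#' Weighted average shortest path length
#'
#' Edge lengths are reciprocal weights (strong synapses are short), pairwise
#' distances are shortest-path lengths, and L_w averages the distance over
#' ordered reachable pairs. Unreachable pairs are excluded and their share is
#' reported. Low L_w means efficient global information transmission.
#'
#' @param g A `weighted_graph_view`.
#' @return List with `l_w`, `reachable_fraction`, `defined`.
#' @export
weighted_spl <- function(g) {
  stopifnot(inherits(g, "weighted_graph_view"))
  if (g$n < 2) stop_input("need at least 2 nodes")
  if (!any(g$adjacency)) {
    return(list(l_w = NA_real_, reachable_fraction = 0, defined = FALSE))
  }
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  # igraph orders edge attributes by its own edge list; build lengths there
  el <- igraph::as_edgelist(ig)
  d <- igraph::distances(ig, weights = 1 / g$weights[el])
  d <- d[row(d) != col(d)]
  reach <- is.finite(d)
  list(l_w = mean(d[reach]),
       reachable_fraction = mean(reach),
       defined = TRUE)
}
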