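#' Pearson correlation matrix between regional BOLD series
#'
#' Computes the region-by-region Pearson correlation of a BOLD matrix: for
#' regions i and j with series \eqn{x_i(t)}, \eqn{x_j(t)} over T volumes,
#' \deqn{R_{ij} = \frac{\sum_t (x_i(t)-\bar x_i)(x_j(t)-\bar x_j)}
#'   {\sqrt{\sum_t (x_i(t)-\bar x_i)^2\,\sum_t (x_j(t)-\bar x_j)^2}}.}
#' Entries near |R| = 1 indicate strong functional coupling between the two
#' regions.
#'
#' @param bold A [bold_matrix()].
#' @return A symmetric correlation matrix with unit diagonal, class
#'   `correlation_matrix`.
#' @export
compute_correlation_matrix <- function(bold) {
  stopifnot(inherits(bold, "bold_matrix"))
  v <- apply(bold, 1, stats::var)
  if (any(v == 0)) {
    bad <- rownames(bold)[which(v == 0)]
    stop_input("zero-variance region(s): ", paste(bad, collapse = ", "),
               "; correlation is undefined for a constant series")
  }
  r <- stats::cor(t(unclass(bold)))
  # guard against round-off outside [-1, 1]
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  structure(r, class = c("correlation_matrix", "matrix", "array"))
}

#' Threshold a correlation matrix into a functional graph
#'
#' An edge joins regions i and j when their coupling exceeds the threshold
#' `x_th`. By default the magnitude |R_ij| is compared (negative correlations
#' count as coupling); `mode = "signed"` compares the raw R_ij instead.
#' The comparison is strict (> x_th).
#'
#' @param corr A `correlation_matrix`.
#' @param x_th Threshold in \[0, 1\]. Default 0.3, the value at which group
#'   densities across subjects are least variable while staying inside the
#'   biological brain-network density range.
#' @param mode `"abs"` (default) or `"signed"`.
#' @return A [topology()] whose `meta` records the threshold and mode.
#' @export
build_functional_graph <- function(corr, x_th = 0.3, mode = c("abs", "signed")) {
  mode <- match.arg(mode)
  assert_scalar_number(x_th, "x_th", lower = 0, upper = 1)
  r <- unclass(corr)
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  cmp <- if (mode == "abs") abs(r) else r
  cmp[lower.tri(cmp, diag = TRUE)] <- -Inf
  idx <- which(cmp > x_th, arr.ind = TRUE)
  topology(nrow(r), idx,
           meta = list(generator = "fbn_threshold", x_th = x_th, mode = mode))
}

#' Network density
#'
#' Ratio of the number of edges present to the maximum possible
#' \eqn{n(n-1)/2} for an undirected simple graph.
#'
#' @param top A [topology()].
#' @return Density in \[0, 1\].
#' @export
network_density <- function(top) {
  stopifnot(inherits(top, "topology"))
  if (top$n_nodes < 2) stop_input("density needs at least 2 nodes")
  nrow(top$edges) / (top$n_nodes * (top$n_nodes - 1) / 2)
}

#' Density as a function of the correlation threshold
#'
#' Sweeps the edge threshold over \[0, 1\] and reports, at each value, the
#' mean and standard deviation of graph density across subjects. Used to pick
#' a threshold whose densities fall inside the biological range while varying
#' least across subjects.
#'
#' @param corrs A list of `correlation_matrix` objects (one per subject), or a
#'   single matrix.
#' @param step Threshold increment, default 0.05.
#' @param mode Passed to [build_functional_graph()].
#' @return A tibble with columns `x_th`, `mean_density`, `sd_density`,
#'   class `density_sweep`.
#' @export
threshold_density_sweep <- function(corrs, step = 0.05, mode = "abs") {
  if (inherits(corrs, "correlation_matrix")) corrs <- list(corrs)
  if (length(corrs) < 1) stop_input("need at least one correlation matrix")
  assert_scalar_number(step, "step", lower = 1e-9, upper = 1)
  ths <- seq(0, 1, by = step)
  dens <- vapply(ths, function(th) {
    d <- vapply(corrs, function(cc) {
      network_density(build_functional_graph(cc, th, mode = mode))
    }, numeric(1))
    c(mean(d), stats::sd(d) %||% 0)
  }, numeric(2))
  out <- tibble::tibble(
    x_th = ths,
    mean_density = dens[1, ],
    sd_density = ifelse(is.na(dens[2, ]), 0, dens[2, ])
  )
  class(out) <- c("density_sweep", class(out))
  out
}

#' Small-world index
#'
#' \eqn{\delta = (C/C_{rand}) / (L/L_{rand})}, where C and L are the binary
#' average clustering coefficient and characteristic path length of the graph
#' and the reference values are means over uniform random graphs with the same
#' node and edge counts. \eqn{\delta > 1} marks small-world organisation.
#'
#' @param top A connected [topology()].
#' @param n_reference Number of random reference graphs (default 20).
#' @param seed Integer seed controlling the reference sample.
#' @param max_retries Resampling budget for reference graphs whose path length
#'   is undefined (disconnected draws).
#' @return The scalar delta.
#' @export
small_world_index <- function(top, n_reference = 20, seed = 1,
                              max_retries = 100) {
  stopifnot(inherits(top, "topology"), n_reference >= 1)
  g <- as_igraph(top)
  if (!igraph::is_connected(g)) {
    stop_input("small-world index requires a connected graph")
  }
  cc <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  pl <- igraph::mean_distance(g)
  n <- top$n_nodes
  m <- nrow(top$edges)
  with_seed(seed, {
    cc_r <- numeric(n_reference)
    pl_r <- numeric(n_reference)
    for (i in seq_len(n_reference)) {
      tries <- 0
      repeat {
        gr <- igraph::sample_gnm(n, m)
        if (igraph::is_connected(gr)) break
        tries <- tries + 1
        if (tries > max_retries) {
          stop_input("could not sample a connected reference graph; ",
                     "the graph is too sparse for matched G(n,m) references")
        }
      }
      cc_r[i] <- igraph::transitivity(gr, type = "localaverage",
                                      isolates = "zero")
      pl_r[i] <- igraph::mean_distance(gr)
    }
    (cc / mean(cc_r)) / (pl / mean(pl_r))
  })
}

#' Largest connected component of a topology
#'
#' Path-based graph metrics (characteristic path length, small-world index)
#' are conventionally computed on the largest component when a thresholded
#' functional graph is disconnected. Nodes are re-indexed consecutively.
#'
#' @param top A [topology()].
#' @return A [topology()] restricted to the largest component; `meta` gains
#'   `component_of` with the original node count.
#' @export
largest_component <- function(top) {
  g <- as_igraph(top)
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  remap <- integer(top$n_nodes)
  remap[keep] <- seq_along(keep)
  sel <- top$edges[, 1] %in% keep & top$edges[, 2] %in% keep
  meta <- top$meta
  meta$component_of <- top$n_nodes
  topology(length(keep),
           cbind(remap[top$edges[sel, 1]], remap[top$edges[sel, 2]]),
           meta = meta)
}

# Hurwitz zeta sum_{k>=0} (a+k)^(-s), s > 1, via direct summation plus an
# Euler-Maclaurin tail.
hurwitz_zeta <- function(s, a, n_terms = 1000) {
  k <- 0:(n_terms - 1)
  head <- sum((a + k)^(-s))
  b <- a + n_terms
  tail <- b^(1 - s) / (s - 1) + 0.5 * b^(-s) + s / 12 * b^(-s - 1)
  head + tail
}

#' Scale-free (power-law) exponent of the degree distribution
#'
#' Fits \eqn{P(k) \propto k^{-\gamma}} to the node degrees. The default is the
#' discrete maximum-likelihood estimator with `x_min` equal to the smallest
#' positive degree: \eqn{\hat\gamma} maximises
#' \eqn{-n\log\zeta(\gamma, x_{min}) - \gamma\sum\log k_i}. A least-squares
#' fit to the log-log degree histogram is available as an alternative.
#' Exponents between 2 and 3 indicate scale-free organisation.
#'
#' @param top A [topology()], or a numeric degree sequence.
#' @param x_min Smallest degree included in the fit; default the minimum
#'   positive degree.
#' @param method `"mle"` (default) or `"ls"`.
#' @return A list with `gamma`, `x_min`, `n_tail`, `defined`, `method`.
#'   A degenerate degree distribution (fewer than 3 distinct values) yields
#'   `defined = FALSE` and `gamma = NA`.
#' @export
scale_free_exponent <- function(top, x_min = NULL, method = c("mle", "ls")) {
  method <- match.arg(method)
  deg <- if (inherits(top, "topology")) {
    tabulate(c(top$edges), nbins = top$n_nodes)
  } else {
    as.numeric(top)
  }
  deg <- deg[deg > 0]
  if (length(unique(deg)) < 3) {
    return(list(gamma = NA_real_, x_min = x_min %||% NA_real_,
                n_tail = 0L, defined = FALSE, method = method))
  }
  x_min <- x_min %||% min(deg)
  k <- deg[deg >= x_min]
  if (method == "mle") {
    nll <- function(s) length(k) * log(hurwitz_zeta(s, x_min)) + s * sum(log(k))
    gamma <- stats::optimize(nll, c(1.05, 8))$minimum
  } else {
    tab <- table(k)
    x <- as.numeric(names(tab))
    y <- as.numeric(tab) / length(k)
    fit <- stats::lm(log(y) ~ log(x))
    gamma <- -unname(stats::coef(fit)[2])
  }
  list(gamma = gamma, x_min = x_min, n_tail = length(k), defined = TRUE,
       method = method)
}
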