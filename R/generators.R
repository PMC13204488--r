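#' Watts-Strogatz small-world topology
#'
#' Builds a ring lattice of `n` nodes each joined to its `k/2` nearest
#' neighbours on either side, then visits every lattice edge once and, with
#' probability `p`, replaces (u, v) by (u, w) where w is drawn uniformly from
#' the nodes, avoiding self-loops and duplicate edges. `p = 0` leaves the
#' regular lattice, `p = 1` gives a random graph; intermediate values give
#' small-world graphs. The edge count is always `n * k / 2`.
#'
#' @param n Number of nodes (`n > k`).
#' @param k Even number of nearest neighbours per node.
#' @param p Rewiring probability in \[0, 1\].
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A [topology()].
#' @export
generate_ws_topology <- function(n, k, p, seed = 1) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2 || k %% 2 != 0) stop_input("`k` must be an even integer >= 2")
  if (n <= k) stop_input("`n` must exceed `k`")
  assert_scalar_number(p, "p", lower = 0, upper = 1)
  adj <- matrix(FALSE, n, n)
  edges <- matrix(0L, n * k / 2, 2)
  row <- 1L
  for (j in seq_len(k / 2)) {
    for (u in seq_len(n)) {
      v <- ((u - 1L + j) %% n) + 1L
      edges[row, ] <- c(u, v)
      adj[u, v] <- adj[v, u] <- TRUE
      row <- row + 1L
    }
  }
  with_seed(seed, {
    for (e in seq_len(nrow(edges))) {
      if (stats::runif(1) < p) {
        u <- edges[e, 1]; v <- edges[e, 2]
        # candidate targets: anything but u itself and u's current neighbours
        free <- which(!adj[u, ] & seq_len(n) != u)
        if (length(free) == 0) next  # u saturated; keep the edge
        w <- free[sample.int(length(free), 1)]
        adj[u, v] <- adj[v, u] <- FALSE
        adj[u, w] <- adj[w, u] <- TRUE
        edges[e, ] <- c(u, w)
      }
    }
  })
  topology(n, edges, meta = list(generator = "watts_strogatz",
                                 n = n, k = k, p = p, seed = seed))
}

#' Barabasi-Albert scale-free topology
#'
#' Starts from a complete graph on `m0` nodes; each subsequent node attaches
#' `me` edges to existing nodes chosen with probability proportional to their
#' current degree, avoiding duplicates and self-loops. Produces a power-law
#' degree distribution with asymptotic exponent close to 3.
#'
#' @param m0 Initial (fully connected) node count.
#' @param me Edges attached per new node (`1 <= me <= m0`).
#' @param n Total node count (`n >= m0`).
#' @param seed Integer seed; deterministic given the seed.
#' @return A [topology()] with `m0*(m0-1)/2 + me*(n-m0)` edges.
#' @export
generate_ba_topology <- function(m0, me, n, seed = 1) {
  m0 <- as.integer(m0); me <- as.integer(me); n <- as.integer(n)
  if (me < 1 || me > m0) stop_input("need 1 <= me <= m0")
  if (n < m0) stop_input("need n >= m0")
  base <- t(utils::combn(m0, 2))
  if (n == m0) {
    return(topology(n, base, meta = list(generator = "barabasi_albert",
                                         m0 = m0, me = me, n = n, seed = seed)))
  }
  edges <- matrix(0L, nrow(base) + me * (n - m0), 2)
  edges[seq_len(nrow(base)), ] <- base
  deg <- integer(n)
  deg[seq_len(m0)] <- m0 - 1L
  row <- nrow(base)
  with_seed(seed, {
    for (i in (m0 + 1L):n) {
      targets <- integer(0)
      existing <- seq_len(i - 1L)
      while (length(targets) < me) {
        cand <- sample(existing, 1, prob = deg[existing])
        if (!(cand %in% targets)) targets <- c(targets, cand)
      }
      for (t in targets) {
        row <- row + 1L
        edges[row, ] <- c(t, i)
        deg[t] <- deg[t] + 1L
      }
      deg[i] <- me
    }
  })
  topology(n, edges, meta = list(generator = "barabasi_albert",
                                 m0 = m0, me = me, n = n, seed = seed))
}
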