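# Independent oracles used across the suite. Each is a direct, naive
# evaluation of the defining formula, kept separate from the package's
# implementation paths.

# Pearson correlation, element-wise from the defining sum
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# DTW minimum cost by exhaustive recursion over all monotone paths
dtw_bruteforce <- function(d) {
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(d[1, 1])
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    d[i, j] + best
  }
  rec(nrow(d), ncol(d))
}

euclid_cost <- function(a, b) {
  outer(seq_len(ncol(a)), seq_len(ncol(b)),
        Vectorize(function(i, j) sqrt(sum((a[, i] - b[, j])^2))))
}

# weighted clustering coefficient by direct triple loop over all node triples
weighted_cc_bruteforce <- function(w) {
  n <- nrow(w)
  a <- w > 0
  terms <- numeric(n)
  for (i in seq_len(n)) {
    d_i <- sum(a[i, ])
    if (d_i < 2) next
    tot <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j != i && k != i && j != k && a[i, j] && a[j, k] && a[k, i]) {
        tot <- tot + (w[i, j] + w[i, k]) / 2
      }
    }
    terms[i] <- tot / (sum(w[i, ]) * (d_i - 1))
  }
  mean(terms)
}

# shortest path by exhaustive simple-path enumeration, lengths 1/weight
spl_pair_bruteforce <- function(w, from, to) {
  n <- nrow(w)
  best <- Inf
  dfs <- function(cur, visited, len) {
    if (len >= best) return()
    if (cur == to) { best <<- min(best, len); return() }
    for (k in seq_len(n)) {
      if (w[cur, k] > 0 && !visited[k]) {
        visited[k] <- TRUE
        dfs(k, visited, len + 1 / w[cur, k])
        visited[k] <- FALSE
      }
    }
  }
  vis <- rep(FALSE, n); vis[from] <- TRUE
  dfs(from, vis, 0)
  best
}

weighted_spl_bruteforce <- function(w) {
  n <- nrow(w)
  d <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) d <- c(d, spl_pair_bruteforce(w, i, j))
  }
  list(l_w = mean(d[is.finite(d)]), reachable_fraction = mean(is.finite(d)))
}

# random symmetric non-negative weight matrix with edge probability p
random_weight_matrix <- function(n, p = 0.5) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) w[i, j] <- w[j, i] <- stats::runif(1, 0.1, 2)
  }
  w
}

# one-way ANOVA from the textbook sum-of-squares decomposition
anova_oracle <- function(groups) {
  y <- unlist(groups)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(y) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(f = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE),
       ssb = ssb, ssw = ssw, sst = sum((y - gm)^2))
}

# exact discrete power-law (zeta) sampler by inverse CDF
sample_discrete_powerlaw <- function(n, gamma, x_min = 1, k_max = 1e5) {
  k <- x_min:k_max
  p <- k^(-gamma)
  sample(k, n, replace = TRUE, prob = p / sum(p))
}

# tiny deterministic waveform for encoder tests
toy_waveform <- function(duration_s = 0.4, sample_rate = 12500, freq = 700) {
  tt <- seq_len(round(duration_s * sample_rate)) / sample_rate
  waveform(0.8 * sin(2 * pi * freq * tt) * (0.5 - 0.5 * cos(2 * pi * tt / max(tt))),
           sample_rate)
}
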