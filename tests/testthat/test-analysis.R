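test_that("firing counts conserve spikes and match a double loop", {
  set.seed(9)
  m <- matrix(rbinom(20 * 300, 1, 0.05), 20, 300)
  r <- spike_raster(m, 0.001)  # 1 ms steps
  fc <- firing_counts(r, bin = 10)
  expect_equal(sum(fc), sum(m))
  # brute force: double loop over bins and steps
  manual <- vapply(seq_len(30), function(b) {
    sum(m[, ((b - 1) * 10 + 1):(b * 10)])
  }, numeric(1))
  expect_equal(fc, manual, ignore_attr = TRUE)
  expect_equal(sum(firing_counts(spike_raster(matrix(0L, 5, 100), 0.001))), 0)
  expect_error(firing_counts(r, bin = 1000), "exceeds")
})

test_that("one-way ANOVA matches the hand formula and flags degeneracy", {
  a <- oneway_anova(list(A = c(1, 2), B = c(3, 4)))
  expect_equal(a$f_value, 8)
  expect_equal(a$df_between, 1)
  expect_equal(a$df_within, 2)
  expect_equal(a$ss_between, 4)
  expect_equal(a$ss_within, 1)
  # random groups against the sum-of-squares oracle
  set.seed(10)
  for (i in 1:20) {
    groups <- lapply(1:4, function(k) rnorm(sample(3:8, 1), mean = k / 2))
    got <- oneway_anova(groups)
    want <- anova_oracle(groups)
    expect_equal(got$f_value, want$f, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
    # decomposition identity
    expect_equal(got$ss_between + got$ss_within, want$sst, tolerance = 1e-10)
  }
  # zero within-group variance
  d <- oneway_anova(list(c(0, 0), c(1, 1)))
  expect_true(d$degenerate)
  expect_true(is.na(d$f_value))
  expect_error(oneway_anova(list(c(1, 2))), "2 groups")
  expect_error(oneway_anova(list(1, c(2, 3))), ">= 2 values")
  expect_named(tidy(a),
               c("f_value", "p_value", "df_between", "df_within",
                 "ss_between", "ss_within", "degenerate"))
})

test_that("synaptic density counts active synapses per neuron", {
  syn <- tibble::tibble(g = c(rep(0.01, 180), rep(0, 20)))
  expect_equal(synaptic_density(syn, 90), 2)
  expect_equal(synaptic_density(tibble::tibble(g = rep(0, 10)), 5), 0)
  # recount oracle against a simulated synapse table
  res <- initialize_reservoir(generate_ws_topology(30, 4, 0.1, seed = 1),
                              seed = 2)
  set.seed(3)
  inp <- spike_raster(matrix(rbinom(20 * 30, 1, 0.05), 20, 30), 0.01)
  sim <- run_reservoir(res, inp, input_map = 1:20)
  expect_equal(synaptic_density(sim$synapses, 30),
               sum(sim$synapses$g > 0) / 30)
})

test_that("the weighted clustering coefficient matches hand and brute force", {
  fx <- gen_toy_fixtures()
  expect_equal(weighted_cc(fx$triangle$graph), 1)
  expect_equal(weighted_cc(fx$star5$graph), 0)
  set.seed(17)
  for (i in 1:100) {
    w <- random_weight_matrix(sample(4:6, 1))
    g <- weighted_graph_view(w)
    expect_equal(weighted_cc(g), weighted_cc_bruteforce(w), tolerance = 1e-12)
  }
})

test_that("uniform weights reduce the weighted CC to the binary CC", {
  set.seed(18)
  for (i in 1:100) {
    n <- sample(5:9, 1)
    a <- matrix(0, n, n)
    for (p in which(upper.tri(a))) a[p] <- rbinom(1, 1, 0.5)
    a <- a + t(a)
    g <- weighted_graph_view(a * 0.37)
    cc_bin <- igraph::transitivity(
      igraph::graph_from_adjacency_matrix(a > 0, mode = "undirected"),
      type = "localaverage", isolates = "zero")
    expect_equal(weighted_cc(g), cc_bin, tolerance = 1e-12)
  }
})

test_that("the weighted SPL uses reciprocal-weight lengths and excludes unreachable pairs", {
  # two nodes, one edge of weight g: L_w = 1/g
  w2 <- matrix(c(0, 0.4, 0.4, 0), 2)
  out <- weighted_spl(weighted_graph_view(w2))
  expect_equal(out$l_w, 1 / 0.4)
  expect_equal(out$reachable_fraction, 1)
  # weak direct edge loses to a strong two-hop path
  w3 <- matrix(0, 3, 3)
  w3[1, 2] <- w3[2, 1] <- 0.1          # length 10
  w3[1, 3] <- w3[3, 1] <- 1            # length 1
  w3[3, 2] <- w3[2, 3] <- 1            # length 1
  # pair (1,2) takes the two-hop route: distances {2, 1, 1} each way
  expect_equal(weighted_spl(weighted_graph_view(w3))$l_w, 4 / 3)
  # brute-force agreement on random graphs, including disconnected ones
  set.seed(19)
  for (i in 1:100) {
    w <- random_weight_matrix(5, p = 0.4)
    if (!any(w > 0)) next
    got <- weighted_spl(weighted_graph_view(w))
    want <- weighted_spl_bruteforce(w)
    expect_equal(got$l_w, want$l_w, tolerance = 1e-10)
    expect_equal(got$reachable_fraction, want$reachable_fraction)
  }
  # no edges: undefined flag
  empty <- weighted_graph_view(matrix(0, 3, 3))
  expect_false(weighted_spl(empty)$defined)
})

test_that("raising a weight never increases the weighted SPL", {
  set.seed(20)
  for (i in 1:25) {
    w <- random_weight_matrix(6, p = 0.6)
    if (!any(w > 0)) next
    base <- weighted_spl(weighted_graph_view(w))$l_w
    e <- which(w > 0, arr.ind = TRUE)[1, ]
    w2 <- w
    w2[e[1], e[2]] <- w2[e[2], e[1]] <- w[e[1], e[2]] * 3
    expect_lte(weighted_spl(weighted_graph_view(w2))$l_w, base + 1e-12)
  }
})

test_that("directed synapse tables symmetrize by the mean of both orientations", {
  syn <- tibble::tibble(pre = c(1, 2, 1), post = c(2, 1, 3),
                        g = c(0.4, 0.2, 0.6))
  g <- synapse_graph_view(syn, 3)
  expect_equal(g$weights[1, 2], 0.3)
  expect_equal(g$weights[2, 1], 0.3)
  expect_equal(g$weights[1, 3], 0.3)  # one-way synapse averaged with zero
  expect_true(g$adjacency[1, 3])
  expect_false(g$adjacency[2, 3])
})
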