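toy_state <- function(n = 1) {
  list(v = rep(-65, n), ref = rep(0, n), nparams = neuron_params(), clock = 0)
}

test_that("LIF first-spike time matches the closed-form solution", {
  # constant I = 20 nA from rest: t* = tau_m * ln(RI / (RI - (Vth - Vrest)))
  st <- toy_state()
  dt <- 0.01
  t <- 0
  repeat {
    out <- lif_step(st, 20, dt)
    st <- out$state
    t <- t + dt
    if (out$spiked) break
    if (t > 100) stop("no spike")
  }
  t_star <- 20 * log(20 / (20 - 15))
  expect_lt(abs(t - t_star) / t_star, 0.02)
})

test_that("rest is a fixed point and the refractory clamp holds", {
  st <- toy_state()
  for (i in 1:500) st <- lif_step(st, 0, 0.1)$state
  expect_equal(st$v, -65)
  # drive to spike, then potential stays at reset for tau_ref regardless of input
  st <- toy_state()
  repeat {
    out <- lif_step(st, 50, 0.1)
    st <- out$state
    if (out$spiked) break
  }
  for (i in 1:19) {  # 1.9 ms of the 2 ms refractory period
    st <- lif_step(st, 1000, 0.1)$state
    expect_equal(st$v, -70)
  }
})

test_that("membrane stays bounded under strong bounded input", {
  st <- toy_state(5)
  set.seed(3)
  for (i in 1:6000) {
    st <- lif_step(st, runif(5, 0, 100), 0.1)$state
    expect_true(all(st$v >= -75 & st$v <= -49))
  }
})

test_that("receptor gate reaches the ODE fixed point and gates current", {
  sp <- synapse_params()
  syn <- list(kind = "ex", g = 0.01, r_g = 0)
  # closed gate: far-negative presynaptic potential, negligible binding
  out <- synapse_gate(syn, -65, -65, sp, 0.1)
  expect_lt(abs(out$current), 1e-5)
  # saturated gate H ~ 1: r_g -> alpha/(alpha+beta) = 2/3
  r <- 0
  for (i in 1:1000) {  # 10 / beta time units at dt = 0.01
    r <- synapse_gate(list(kind = "ex", g = 0.01, r_g = r),
                      1000, -65, sp, 0.01)$r_g
  }
  expect_lt(abs(r - 2 / 3), 1e-4)
  # zero driving force: no current at the reversal potential
  expect_equal(synapse_gate(list(kind = "ex", g = 0.01, r_g = 0.5),
                            1000, sp$e_syn_ex, sp, 0.1)$current, 0)
  # r_g = 0 gives no current regardless of potentials
  expect_equal(synapse_gate(list(kind = "in", g = 0.015, r_g = 0),
                            30, 0, sp, 0)$current, 0)
})

test_that("STDP decay, pairing increments and clipping follow the rule", {
  sp <- synapse_params()
  syn <- list(kind = "ex", g = 0.01)
  # exponential decay with tau_ex = 3 ms
  for (t in c(1, 3, 10)) {
    expect_lt(abs(stdp_update(syn, "decay", sp, dt_elapsed = t)$g -
                    0.01 * exp(-t / 3)), 1e-6)
  }
  expect_lt(abs(stdp_update(list(kind = "in", g = 0.01), "decay", sp,
                            dt_elapsed = 5)$g - 0.01 * exp(-1)), 1e-6)
  # near-coincident excitatory potentiation: A+ * g_max = 1.5e-3
  g1 <- stdp_update(list(kind = "ex", g = 0.001), "pairing", sp,
                    delta_t = -1e-9)$g
  expect_equal(g1 - 0.001, 0.1 * 0.015, tolerance = 1e-9)
  # clipping at both ends
  expect_equal(stdp_update(list(kind = "ex", g = 0.0149), "pairing", sp,
                           delta_t = -0.1)$g, 0.015)
  expect_equal(stdp_update(list(kind = "ex", g = 1e-5), "pairing", sp,
                           delta_t = 0.1)$g, 0)
  # inhibitory signs: pre-before-post depresses, post-before-pre potentiates
  expect_lt(stdp_update(list(kind = "in", g = 0.01), "pairing", sp,
                        delta_t = -1)$g, 0.01)
  expect_gt(stdp_update(list(kind = "in", g = 0.01), "pairing", sp,
                        delta_t = 1)$g, 0.01)
})

test_that("reservoir initialization honours topology, delays and determinism", {
  top <- generate_ws_topology(90, 8, 0.1, seed = 2)
  res <- initialize_reservoir(top, seed = 4)
  expect_equal(length(res$v), 90)
  expect_equal(nrow(res$synapses), 2 * nrow(top$edges))
  expect_true(all(res$synapses$delay >= 0.1 & res$synapses$delay <= 40))
  expect_true(all(res$synapses$g > 0 & res$synapses$g <= 0.015))
  expect_true(all(res$synapses$r_g == 0))
  expect_equal(sum(res$is_excitatory), 72)
  # outgoing synapses inherit the neuron label (Dale's principle)
  expect_equal(res$synapses$kind,
               ifelse(res$is_excitatory[res$synapses$pre], "ex", "in"))
  res2 <- initialize_reservoir(top, seed = 4)
  expect_identical(res$synapses, res2$synapses)
  expect_false(identical(res$synapses$delay,
                         initialize_reservoir(top, seed = 5)$synapses$delay))
})

test_that("the compiled run is silent without input, deterministic, and clipped", {
  top <- generate_ws_topology(90, 8, 0.1, seed = 2)
  res <- initialize_reservoir(top, seed = 4)
  z <- spike_raster(matrix(0L, 39, 60), 0.01)
  expect_equal(sum(run_reservoir(res, z, 1:39)$raster), 0)
  set.seed(8)
  inp <- spike_raster(matrix(rbinom(39 * 60, 1, 0.05), 39, 60), 0.01)
  a <- run_reservoir(res, inp, 1:39, record_weights = TRUE,
                     snapshot_every = 500)
  b <- run_reservoir(res, inp, 1:39, record_weights = TRUE,
                     snapshot_every = 500)
  expect_identical(unclass(a$raster), unclass(b$raster))
  expect_identical(a$synapses$g, b$synapses$g)
  expect_gt(sum(a$raster), 0)
  # 600 ms clipping audit over recorded snapshots and final weights
  expect_true(all(a$snapshots >= 0 & a$snapshots <= 0.015))
  expect_true(all(a$synapses$g >= 0 & a$synapses$g <= 0.015))
  expect_true(all(a$v_final >= -75 & a$v_final <= -49))
})

test_that("a suprathreshold input pulse fires the target neuron in-window", {
  res <- initialize_reservoir(topology(2, cbind(1, 2)), seed = 1)
  one <- spike_raster(matrix(c(1L, rep(0L, 29)), 1, 30), 0.01)
  sim <- run_reservoir(res, one, input_map = 1)
  first <- which(sim$raster[1, ] == 1)[1]
  expect_lte(first * sim$dt, 1)  # within the 1 ms pulse
})

test_that("halving dt changes the spike count of a fixed run by < 5%", {
  top <- generate_ws_topology(90, 8, 0.1, seed = 2)
  res <- initialize_reservoir(top, seed = 4)
  set.seed(8)
  inp <- spike_raster(matrix(rbinom(39 * 60, 1, 0.05), 39, 60), 0.01)
  n1 <- sum(run_reservoir(res, inp, 1:39, dt = 0.1)$raster)
  n2 <- sum(run_reservoir(res, inp, 1:39, dt = 0.05)$raster)
  expect_lt(abs(n1 - n2) / n1, 0.05)
})
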