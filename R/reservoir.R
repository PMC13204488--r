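#' LIF neuron parameters
#'
#' Leaky integrate-and-fire constants. Defaults follow the standard cortical
#' parameterisation used throughout the package: membrane time constant 20 ms,
#' resting potential -65 mV, firing threshold -50 mV, reset -70 mV, membrane
#' resistance 1 MOhm, absolute refractory period 2 ms. Membrane dynamics are
#' \deqn{\tau_m \frac{dV}{dt} = -(V - V_{rest}) + R_m I_{syn}(t),}
#' with a spike and reset to `v_reset` when V reaches `v_th`, followed by
#' `tau_ref` ms clamped at `v_reset` ignoring input.
#'
#' @param tau_m Membrane time constant, ms.
#' @param v_rest,v_th,v_reset Resting, threshold and reset potentials, mV
#'   (must satisfy `v_reset <= v_rest < v_th`).
#' @param r_m Membrane resistance, MOhm (so `r_m * I[nA]` is mV).
#' @param tau_ref Absolute refractory period, ms.
#' @return A list of class `neuron_params`.
#' @export
neuron_params <- function(tau_m = 20, v_rest = -65, v_th = -50,
                          v_reset = -70, r_m = 1, tau_ref = 2) {
  if (!(v_reset <= v_rest && v_rest < v_th)) {
    stop_input("need v_reset <= v_rest < v_th")
  }
  if (tau_m <= 0 || tau_ref <= 0 || r_m <= 0) {
    stop_input("time constants and resistance must be positive")
  }
  structure(as.list(environment()), class = "neuron_params")
}

#' Synapse and plasticity parameters
#'
#' Receptor-kinetics synapse with spike-timing-dependent plasticity and
#' conduction delay. Defaults: excitatory/inhibitory reversal potentials
#' 0 / -70 mV; neurotransmitter binding (alpha) and unbinding (beta) rates
#' 2, 1 per ms (excitatory) and 0.9, 0.1 (inhibitory); weight decay constants
#' 3 ms (ex) and 5 ms (in); weight cap `g_max` 0.015; STDP magnitudes
#' A+ = 0.1, A- = 0.105 (excitatory), B+ = 0.02, B- = 0.03 (inhibitory) with
#' 20 ms windows; conduction delays Poisson-distributed with 10 ms mean,
#' clipped to \[0.1, 40\] ms.
#'
#' `v_scale` and `spike_peak` parameterise the neurotransmitter gate
#' \eqn{H = 1/(1 + e^{-V_{pre}(t - delay)/v_{scale}})}: the delayed
#' presynaptic potential is taken as a `spike_peak` mV overshoot for
#' `spike_width` ms after each presynaptic spike (subthreshold LIF potentials
#' are always far negative, so the gate opens only on spikes).
#'
#' @param e_syn_ex,e_syn_in Reversal potentials, mV.
#' @param alpha_ex,alpha_in,beta_ex,beta_in Binding/unbinding rates, 1/ms.
#' @param tau_ex,tau_in Weight decay constants, ms.
#' @param g_max Maximum synaptic weight (clipping bound).
#' @param a_plus,a_minus,b_plus,b_minus STDP modulation magnitudes.
#' @param tau_plus,tau_minus STDP window constants, ms.
#' @param delay_min,delay_max,delay_mean Conduction delay range and Poisson
#'   mean, ms.
#' @param v_scale Gate slope, mV.
#' @param spike_peak,spike_width Presynaptic spike waveform seen by the gate:
#'   peak potential (mV) and duration (ms).
#' @return A list of class `synapse_params`.
#' @export
synapse_params <- function(e_syn_ex = 0, e_syn_in = -70,
                           alpha_ex = 2, alpha_in = 0.9,
                           beta_ex = 1, beta_in = 0.1,
                           tau_ex = 3, tau_in = 5,
                           g_max = 0.015,
                           a_plus = 0.1, a_minus = 0.105,
                           b_plus = 0.02, b_minus = 0.03,
                           tau_plus = 20, tau_minus = 20,
                           delay_min = 0.1, delay_max = 40, delay_mean = 10,
                           v_scale = 5, spike_peak = 30, spike_width = 1) {
  if (g_max <= 0) stop_input("`g_max` must be positive")
  if (delay_min <= 0 || delay_max < delay_min) {
    stop_input("invalid delay range")
  }
  if (any(c(a_plus, a_minus, b_plus, b_minus) < 0)) {
    stop_input("STDP magnitudes must be non-negative")
  }
  structure(as.list(environment()), class = "synapse_params")
}

#' Build a reservoir from a topology
#'
#' Each undirected edge becomes two directed synapses (one per orientation).
#' Neurons are assigned excitatory or inhibitory labels (all outgoing synapses
#' of a neuron inherit its label, Dale-consistent), conduction delays are
#' drawn from a Poisson distribution with mean `delay_mean` and clipped to
#' \[`delay_min`, `delay_max`\] ms, initial weights are uniform on
#' (0, `g_max`\], receptor states start at zero and membranes at rest.
#' Deterministic given `seed`.
#'
#' @param top A [topology()].
#' @param nparams A [neuron_params()].
#' @param sparams A [synapse_params()].
#' @param excitatory_fraction Fraction of excitatory neurons (default 0.8).
#' @param seed Integer seed.
#' @return A `reservoir_state`: list with membrane potentials `v`, refractory
#'   timers `ref`, a `synapses` tibble (`pre`, `post`, `kind`, `g`, `delay`,
#'   `r_g`, `last_pre`, `last_post`), `clock`, parameters and seed.
#' @export
initialize_reservoir <- function(top, nparams = neuron_params(),
                                 sparams = synapse_params(),
                                 excitatory_fraction = 0.8, seed = 1) {
  stopifnot(inherits(top, "topology"))
  if (nrow(top$edges) == 0) stop_input("topology has no edges")
  if (excitatory_fraction <= 0 || excitatory_fraction >= 1) {
    stop_input("`excitatory_fraction` must be in (0, 1)")
  }
  n <- top$n_nodes
  with_seed(seed, {
    n_ex <- max(1L, round(excitatory_fraction * n))
    is_ex <- rep(FALSE, n)
    is_ex[sample.int(n, n_ex)] <- TRUE
    pre <- c(top$edges[, 1], top$edges[, 2])
    post <- c(top$edges[, 2], top$edges[, 1])
    m <- length(pre)
    delay <- pmin(pmax(stats::rpois(m, sparams$delay_mean),
                       sparams$delay_min), sparams$delay_max)
    g <- stats::runif(m) * sparams$g_max
    syn <- tibble::tibble(
      pre = pre, post = post,
      kind = ifelse(is_ex[pre], "ex", "in"),
      g = g, delay = delay, r_g = 0,
      last_pre = NA_real_, last_post = NA_real_
    )
    structure(list(
      v = rep(nparams$v_rest, n),
      ref = rep(0, n),
      synapses = syn,
      is_excitatory = is_ex,
      clock = 0,
      nparams = nparams,
      sparams = sparams,
      seed = seed,
      topology = top
    ), class = "reservoir_state")
  })
}

#' @export
print.reservoir_state <- function(x, ...) {
  cat(sprintf("<reservoir_state> %d neurons (%d excitatory), %d synapses, clock %.1f ms\n",
              length(x$v), sum(x$is_excitatory), nrow(x$synapses), x$clock))
  invisible(x)
}

#' One forward-Euler LIF step
#'
#' Advances all membrane potentials by `dt` under the injected currents.
#' Refractory neurons stay clamped at the reset potential and ignore input;
#' a neuron crossing threshold emits a spike, resets, and starts its
#' refractory timer.
#'
#' @param state A `reservoir_state` (only `v`, `ref` and `nparams` are used).
#' @param injected_current Per-neuron current, nA.
#' @param dt Step, ms (`dt <= tau_ref`).
#' @return List with the updated `state` and logical `spiked`.
#' @export
lif_step <- function(state, injected_current, dt) {
  p <- state$nparams
  if (dt <= 0 || dt > p$tau_ref) stop_input("need 0 < dt <= tau_ref")
  if (!all(is.finite(injected_current))) stop_input("non-finite current")
  v <- state$v
  ref <- state$ref
  active <- ref <= 0
  v[active] <- v[active] + dt / p$tau_m *
    (-(v[active] - p$v_rest) + p$r_m * injected_current[active])
  spiked <- active & v >= p$v_th
  v[spiked] <- p$v_reset
  ref[spiked] <- p$tau_ref
  refractory <- !active
  v[refractory] <- p$v_reset
  ref[refractory] <- ref[refractory] - dt
  state$v <- v
  state$ref <- ref
  state$clock <- state$clock + dt
  list(state = state, spiked = spiked)
}

#' Receptor-kinetics synapse gate
#'
#' Advances the bound-receptor fraction of a synapse by one Euler step of
#' \eqn{dr_g/dt = \alpha H (1 - r_g) - \beta r_g} with the logistic
#' neurotransmitter gate \eqn{H = 1/(1+e^{-v_{pre}(t-delay)/v_{scale}})},
#' and returns the synaptic current \eqn{I = g\, r_g\, (E_{syn} - v_{post})}.
#' Vectorised over synapses.
#'
#' @param syn A synapse row/tibble with `kind`, `g`, `r_g`.
#' @param v_pre_delayed Delayed presynaptic potential(s), mV.
#' @param v_post Postsynaptic potential(s), mV.
#' @param sparams A [synapse_params()].
#' @param dt Step, ms.
#' @return List with updated `r_g` and `current` (nA).
#' @export
synapse_gate <- function(syn, v_pre_delayed, v_post, sparams, dt) {
  ex <- syn$kind == "ex"
  a <- ifelse(ex, sparams$alpha_ex, sparams$alpha_in)
  b <- ifelse(ex, sparams$beta_ex, sparams$beta_in)
  e_syn <- ifelse(ex, sparams$e_syn_ex, sparams$e_syn_in)
  h <- 1 / (1 + exp(-v_pre_delayed / sparams$v_scale))
  r_g <- syn$r_g + dt * (a * h * (1 - syn$r_g) - b * syn$r_g)
  r_g <- pmin(pmax(r_g, 0), 1)
  list(r_g = r_g, current = syn$g * r_g * (e_syn - v_post))
}

#' STDP weight update
#'
#' Implements the plasticity rule: between spikes the weight decays
#' exponentially (`exp(-dt/tau_ex)` per elapsed interval for excitatory
#' synapses, `tau_in` for inhibitory); on a pre/post spike pairing with
#' timing difference `delta_t = t_pre - t_post` the weight gains
#' \eqn{\bar g = w(\Delta t)\,g_{max}} where, for excitatory synapses,
#' \eqn{w = A_+ e^{\Delta t/\tau_+}} when \eqn{\Delta t < 0} (pre before
#' post, potentiation) and \eqn{-A_- e^{-\Delta t/\tau_-}} otherwise; for
#' inhibitory synapses the modulation is \eqn{-B_+ e^{\Delta t/\tau_+}} /
#' \eqn{B_- e^{-\Delta t/\tau_-}}. The result is clipped to \[0, `g_max`\].
#'
#' @param syn A synapse row/tibble with `kind` and `g` (vectorised).
#' @param event `"decay"` or `"pairing"`.
#' @param sparams A [synapse_params()].
#' @param dt_elapsed Elapsed time for decay events, ms.
#' @param delta_t Spike-timing difference `t_pre - t_post` for pairing
#'   events, ms.
#' @return The synapse with updated `g`.
#' @export
stdp_update <- function(syn, event = c("decay", "pairing"), sparams,
                        dt_elapsed = NULL, delta_t = NULL) {
  event <- match.arg(event)
  ex <- syn$kind == "ex"
  g <- syn$g
  if (event == "decay") {
    stopifnot(!is.null(dt_elapsed))
    tau <- ifelse(ex, sparams$tau_ex, sparams$tau_in)
    g <- g * exp(-dt_elapsed / tau)
  } else {
    stopifnot(!is.null(delta_t))
    mod <- ifelse(delta_t < 0,
                  ifelse(ex, sparams$a_plus, -sparams$b_plus) *
                    exp(delta_t / sparams$tau_plus),
                  ifelse(ex, -sparams$a_minus, sparams$b_minus) *
                    exp(-delta_t / sparams$tau_minus))
    g <- g + mod * sparams$g_max
  }
  syn$g <- pmin(pmax(g, 0), sparams$g_max)
  syn
}

#' Run the spiking reservoir on an input raster
#'
#' Event loop over the full network: input spikes are injected as rectangular
#' current pulses into the mapped neurons, delayed presynaptic potentials
#' drive the receptor gates, synaptic currents feed the LIF update, and STDP
#' (pairing on spike events, exponential decay otherwise) shapes the weights
#' throughout the run when `plasticity` is on. The loop is compiled (Rcpp) and
#' deterministic: all randomness lives in [initialize_reservoir()].
#'
#' @param state A `reservoir_state` (left unmodified; the run starts from it).
#' @param input_raster A [spike_raster()] of encoder output.
#' @param input_map Integer vector assigning each input channel to a distinct
#'   reservoir neuron.
#' @param input_amplitude Current per input spike, nA. The default 450 nA
#'   with a 1 ms pulse is suprathreshold from any post-spike state: one input
#'   spike depolarises the target neuron past threshold within the pulse even
#'   from the reset potential, so the input raster is relayed faithfully.
#' @param pulse_width Input pulse width, ms.
#' @param duration Simulated time, ms; defaults to the raster span.
#' @param dt Integration step, ms (default 0.1).
#' @param plasticity Apply STDP during the run (default TRUE).
#' @param record_weights Record the per-step mean weight trace.
#' @param snapshot_every Record full weight snapshots every this many steps
#'   (0 = off).
#' @return A `simulation_result`: list with the reservoir `raster`
#'   ([spike_raster()], neurons x steps), final `synapses` tibble, optional
#'   `weight_trace` tibble and `snapshots` matrix, and the run parameters.
#' @export
run_reservoir <- function(state, input_raster, input_map,
                          input_amplitude = 450, pulse_width = 1,
                          duration = NULL, dt = 0.1,
                          plasticity = TRUE, record_weights = FALSE,
                          snapshot_every = 0) {
  stopifnot(inherits(state, "reservoir_state"),
            inherits(input_raster, "spike_raster"))
  n_ch <- nrow(input_raster)
  input_map <- as.integer(input_map)
  if (length(input_map) != n_ch) {
    stop_input("`input_map` must assign every input channel")
  }
  if (anyDuplicated(input_map) || any(input_map < 1) ||
      any(input_map > length(state$v))) {
    stop_input("`input_map` must be distinct reservoir neuron indices")
  }
  raster_dt_ms <- attr(input_raster, "dt") * 1000
  span <- ncol(input_raster) * raster_dt_ms
  duration <- duration %||% span
  if (duration < span) stop_input("`duration` must cover the raster span")
  ev <- which(unclass(input_raster) == 1L, arr.ind = TRUE)
  events <- cbind(input_map[ev[, 1]],
                  as.integer(round((ev[, 2] - 1) * raster_dt_ms / dt)))
  n_steps <- as.integer(ceiling(duration / dt))
  syn <- state$synapses
  res <- reservoir_run_cpp(
    length(state$v), syn$pre, syn$post, syn$kind == "ex",
    syn$g, syn$delay, syn$r_g,
    state$nparams, state$sparams,
    matrix(as.integer(events), ncol = 2),
    input_amplitude, as.integer(max(1, round(pulse_width / dt))),
    dt, n_steps, isTRUE(plasticity), isTRUE(record_weights),
    as.integer(snapshot_every)
  )
  syn$g <- res$g
  syn$r_g <- res$r_g
  out <- list(
    raster = spike_raster(res$spikes, dt / 1000),
    synapses = syn,
    v_final = res$v,
    weight_trace = if (record_weights) {
      tibble::tibble(time_ms = (seq_len(n_steps)) * dt,
                     mean_g = res$weight_trace)
    },
    snapshots = res$snapshots,
    dt = dt, duration = duration,
    input_map = input_map,
    input_amplitude = input_amplitude, pulse_width = pulse_width
  )
  class(out) <- "simulation_result"
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d neurons x %d steps (dt = %g ms), %d spikes\n",
              nrow(x$raster), ncol(x$raster), x$dt, sum(x$raster)))
  invisible(x)
}
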