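#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// STDP pairing modulation, delta_t = t_pre - t_post (ms).
static inline double pairing_mod(bool ex, double delta_t,
                                 double a_plus, double a_minus,
                                 double b_plus, double b_minus,
                                 double tau_plus, double tau_minus) {
  if (delta_t < 0) {
    double m = std::exp(delta_t / tau_plus);
    return ex ? a_plus * m : -b_plus * m;
  }
  double m = std::exp(-delta_t / tau_minus);
  return ex ? -a_minus * m : b_minus * m;
}

// Full reservoir event loop. Per step: (1) input pulse currents, (2) receptor
// gates + synaptic currents + pre-arrival STDP pairings, (3) exponential
// weight decay, (4) forward-Euler LIF update with reset/refractory,
// (5) post-spike STDP pairings, (6) history bookkeeping for delayed
// presynaptic potentials.
// [[Rcpp::export]]
List reservoir_run_cpp(int n_neurons,
                       IntegerVector syn_pre, IntegerVector syn_post,
                       LogicalVector syn_ex,
                       NumericVector g_in, NumericVector delay_ms,
                       NumericVector rg_in,
                       List nparams, List sparams,
                       IntegerMatrix input_events,
                       double amplitude, int pulse_steps,
                       double dt, int n_steps,
                       bool plasticity, bool record_weights,
                       int snapshot_every) {
  const int n_syn = syn_pre.size();
  const double tau_m = nparams["tau_m"], v_rest = nparams["v_rest"],
               v_th = nparams["v_th"], v_reset = nparams["v_reset"],
               r_m = nparams["r_m"], tau_ref = nparams["tau_ref"];
  const double e_ex = sparams["e_syn_ex"], e_in = sparams["e_syn_in"],
               alpha_ex = sparams["alpha_ex"], alpha_in = sparams["alpha_in"],
               beta_ex = sparams["beta_ex"], beta_in = sparams["beta_in"],
               tau_ex = sparams["tau_ex"], tau_in = sparams["tau_in"],
               g_max = sparams["g_max"],
               a_plus = sparams["a_plus"], a_minus = sparams["a_minus"],
               b_plus = sparams["b_plus"], b_minus = sparams["b_minus"],
               tau_plus = sparams["tau_plus"], tau_minus = sparams["tau_minus"],
               v_scale = sparams["v_scale"], spike_peak = sparams["spike_peak"],
               spike_width = sparams["spike_width"];
  const int spike_width_steps = std::max(1, (int)std::lround(spike_width / dt));
  const double dec_ex = std::exp(-dt / tau_ex), dec_in = std::exp(-dt / tau_in);

  std::vector<double> g(g_in.begin(), g_in.end());
  std::vector<double> rg(rg_in.begin(), rg_in.end());
  std::vector<int> delay_steps(n_syn);
  for (int s = 0; s < n_syn; ++s)
    delay_steps[s] = std::max(1, (int)std::lround(delay_ms[s] / dt));

  std::vector<double> v(n_neurons, v_rest), ref(n_neurons, 0.0);
  std::vector<double> last_pre(n_syn, -1e12), last_post(n_syn, -1e12);
  // synapses grouped by postsynaptic neuron, for post-spike pairings
  std::vector<std::vector<int>> by_post(n_neurons);
  for (int s = 0; s < n_syn; ++s) by_post[syn_post[s] - 1].push_back(s);

  // input pulse edges: +amplitude at start step, -amplitude after the pulse
  std::vector<std::vector<std::pair<int, double>>> in_delta(n_steps + 1);
  for (int e = 0; e < input_events.nrow(); ++e) {
    int nrn = input_events(e, 0) - 1, st = input_events(e, 1);
    if (st < 0 || st >= n_steps) continue;
    in_delta[st].push_back({nrn, amplitude});
    int off = std::min(st + pulse_steps, n_steps);
    in_delta[off].push_back({nrn, -amplitude});
  }

  IntegerMatrix spikes(n_neurons, n_steps);
  NumericMatrix vhist(n_neurons, n_steps);
  std::vector<int> last_spike_step(n_neurons, -1000000000);
  // last spike step at or before t, filled incrementally
  IntegerMatrix lastsp(n_neurons, n_steps);

  NumericVector weight_trace(record_weights ? n_steps : 0);
  int n_snap = snapshot_every > 0 ? n_steps / snapshot_every : 0;
  NumericMatrix snapshots(snapshot_every > 0 ? n_syn : 0, n_snap);
  int snap_col = 0;

  std::vector<double> cur_in(n_neurons, 0.0), i_syn(n_neurons, 0.0);

  for (int t = 0; t < n_steps; ++t) {
    const double now = t * dt;
    for (auto &d : in_delta[t]) cur_in[d.first] += d.second;
    std::fill(i_syn.begin(), i_syn.end(), 0.0);

    for (int s = 0; s < n_syn; ++s) {
      const int pre = syn_pre[s] - 1, post = syn_post[s] - 1;
      const int td = t - delay_steps[s];
      double v_pre_del = v_rest;
      bool pre_arrival = false;
      if (td >= 0) {
        int ls = lastsp(pre, td);
        if (ls >= 0 && td - ls < spike_width_steps) v_pre_del = spike_peak;
        else v_pre_del = vhist(pre, td);
        pre_arrival = spikes(pre, td) == 1;
      }
      const bool ex = syn_ex[s];
      const double h = 1.0 / (1.0 + std::exp(-v_pre_del / v_scale));
      const double a = ex ? alpha_ex : alpha_in, b = ex ? beta_ex : beta_in;
      double r = rg[s] + dt * (a * h * (1.0 - rg[s]) - b * rg[s]);
      rg[s] = r < 0.0 ? 0.0 : (r > 1.0 ? 1.0 : r);
      i_syn[post] += g[s] * rg[s] * ((ex ? e_ex : e_in) - v[post]);

      if (plasticity) {
        g[s] *= ex ? dec_ex : dec_in;
        if (pre_arrival) {
          if (last_post[s] > -1e11) {
            double mod = pairing_mod(ex, now - last_post[s], a_plus, a_minus,
                                     b_plus, b_minus, tau_plus, tau_minus);
            g[s] += mod * g_max;
            g[s] = g[s] < 0.0 ? 0.0 : (g[s] > g_max ? g_max : g[s]);
          }
          last_pre[s] = now;
        }
      }
    }

    for (int i = 0; i < n_neurons; ++i) {
      bool fired = false;
      if (ref[i] > 0.0) {
        ref[i] -= dt;
        v[i] = v_reset;
      } else {
        v[i] += dt / tau_m *
                (-(v[i] - v_rest) + r_m * (i_syn[i] + cur_in[i]));
        if (v[i] >= v_th) {
          fired = true;
          v[i] = v_reset;
          ref[i] = tau_ref;
          last_spike_step[i] = t;
        }
      }
      spikes(i, t) = fired ? 1 : 0;
      vhist(i, t) = v[i];
      lastsp(i, t) = fired ? t : (t > 0 ? lastsp(i, t - 1) : -1);
      if (fired && plasticity) {
        for (int s : by_post[i]) {
          if (last_pre[s] > -1e11) {
            double mod = pairing_mod(syn_ex[s], last_pre[s] - now, a_plus,
                                     a_minus, b_plus, b_minus, tau_plus,
                                     tau_minus);
            g[s] += mod * g_max;
            g[s] = g[s] < 0.0 ? 0.0 : (g[s] > g_max ? g_max : g[s]);
          }
          last_post[s] = now;
        }
      }
    }

    if (record_weights) {
      double sum = 0.0;
      for (int s = 0; s < n_syn; ++s) sum += g[s];
      weight_trace[t] = sum / n_syn;
    }
    if (snapshot_every > 0 && (t + 1) % snapshot_every == 0 &&
        snap_col < n_snap) {
      for (int s = 0; s < n_syn; ++s) snapshots(s, snap_col) = g[s];
      ++snap_col;
    }
  }

  return List::create(
      _["spikes"] = spikes, _["g"] = NumericVector(g.begin(), g.end()),
      _["r_g"] = NumericVector(rg.begin(), rg.end()),
      _["v"] = NumericVector(v.begin(), v.end()),
      _["weight_trace"] = weight_trace, _["snapshots"] = snapshots);
}

// LIF response of independent output neurons to a current matrix
// (neurons x steps). Same dynamics as the reservoir neurons.
// [[Rcpp::export]]
IntegerMatrix lif_response_cpp(NumericMatrix current, double dt,
                               List nparams) {
  const double tau_m = nparams["tau_m"], v_rest = nparams["v_rest"],
               v_th = nparams["v_th"], v_reset = nparams["v_reset"],
               r_m = nparams["r_m"], tau_ref = nparams["tau_ref"];
  const int n = current.nrow(), steps = current.ncol();
  IntegerMatrix spikes(n, steps);
  std::vector<double> v(n, v_rest), ref(n, 0.0);
  for (int t = 0; t < steps; ++t) {
    for (int i = 0; i < n; ++i) {
      if (ref[i] > 0.0) {
        ref[i] -= dt;
        v[i] = v_reset;
      } else {
        v[i] += dt / tau_m * (-(v[i] - v_rest) + r_m * current(i, t));
        if (v[i] >= v_th) {
          spikes(i, t) = 1;
          v[i] = v_reset;
          ref[i] = tau_ref;
        }
      }
    }
  }
  return spikes;
}
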