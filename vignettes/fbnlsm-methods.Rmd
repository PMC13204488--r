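---
title: "Methods: brain-network-constrained spiking reservoirs for spoken-digit recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-network-constrained spiking reservoirs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`fbnlsm` implements a liquid state machine (LSM) whose reservoir wiring is
constrained by a functional brain network (FBN), together with the sparse
spike encoder that feeds it and the analytics used to explain its behaviour.
The pipeline is:

1. **Functional graph** — Pearson correlations between regional BOLD time
   series, thresholded into an undirected binary graph.
2. **Spike encoding** — enhanced MFCC features (13 static + 13 delta +
   13 delta-delta), DTW alignment to a common frame count, per-frame layer
   normalization, and Sigma-Delta modulation into a 39-channel binary raster.
3. **Reservoir** — 90 leaky integrate-and-fire (LIF) neurons wired by the
   graph, with receptor-kinetics synapses, spike-timing-dependent plasticity
   (STDP) and Poisson-distributed conduction delays.
4. **Readout** — one output LIF neuron per class, trained with the remote
   supervised method (ReSuMe) against class-specific template spike trains,
   classified by van Rossum distance to the own-class template.

Everything runs at desk scale on synthetic data produced by the package's own
generators, so no licensed speech corpus or archived fMRI data is needed.

# Functional graph construction

For regions $i, j$ with series $x_i(t)$ over $T$ volumes,
$$R_{ij} = \frac{\sum_t (x_i(t)-\bar x_i)(x_j(t)-\bar x_j)}
  {\sqrt{\sum_t (x_i(t)-\bar x_i)^2 \sum_t (x_j(t)-\bar x_j)^2}},$$
and an edge joins $i$ and $j$ when $|R_{ij}| > X_{th}$ (strict). The absolute
value is the default because strong *negative* coupling is still coupling;
`mode = "signed"` restricts to positive correlations for sensitivity
analyses. The default threshold $X_{th} = 0.3$ keeps group densities inside
the biological brain-network band of 3.6–39.3% while minimising
across-subject variability; `threshold_density_sweep()` reproduces that
analysis at 0.05 steps.

Graph characterisation uses two standard indices. The small-world index
$\delta = (C/C_{rand})/(L/L_{rand})$ compares the binary average clustering
coefficient and characteristic path length against means over 20 uniform
$G(n,m)$ random graphs with matched node and edge counts (disconnected
reference draws are resampled with a bounded retry budget). Because a
thresholded graph can be disconnected, $\delta$ is conventionally evaluated
on the largest component (`largest_component()`). The scale-free exponent
$\gamma$ is fitted to the degree distribution by discrete maximum likelihood,
$\hat\gamma = \arg\min_\gamma\, n \log \zeta(\gamma, x_{min}) +
\gamma \sum_i \log k_i$, with $x_{min}$ defaulting to the smallest positive
degree; a log–log least-squares fit is available as a cross-check. On
finite preferential-attachment graphs the pure power law only holds in the
tail, so recovering the asymptotic exponent 3 requires raising $x_{min}$
above the attachment scale (we use $x_{min} = 8$ in the generator checks).

The Watts–Strogatz generator builds a ring lattice ($n$ nodes, $k$
neighbours) and rewires each original edge $(u, v)$ with probability $p$ to
$(u, w)$, keeping the source endpoint, avoiding self-loops and duplicates;
the edge count $nk/2$ is invariant. The Barabási–Albert generator starts
from a complete graph on $m_0$ nodes and attaches each new node with $m_e$
degree-proportional edges, giving $\binom{m_0}{2} + m_e (n - m_0)$ edges.

# Spike encoding

The front end is a conventional MFCC chain: pre-emphasis 0.97, 25 ms Hamming
windows at a 10 ms hop, FFT magnitude, 26 triangular Mel filters, log
compression and an orthonormal DCT keeping 13 cepstra including $c_0$.
Dynamic features use the central-difference estimator
$$\Delta c_t = \frac{\sum_{n=1}^{N} n\,(c_{t+n} - c_{t-n})}{2\sum_{n=1}^N n^2},
\qquad N = 2,$$
applied twice for the second derivative, with replicate padding at the
edges. The result is a 39-row feature matrix per utterance.

Variable-length utterances are warped to a common frame count with DTW using
the classic three-predecessor recurrence
$D(i,j) = d(i,j) + \min\{D(i{-}1,j), D(i,j{-}1), D(i{-}1,j{-}1)\}$, Euclidean
local distance over 39-dimensional frames and no slope weighting. The
default reference is the uniform time-stretch of the utterance itself, so
alignment reduces to a smooth stretch; output frame $j$ is the mean of all
source frames the optimal path maps to $j$. The common length defaults to
the median training-utterance frame count. Ties in backtracking prefer the
diagonal predecessor; the returned distance is unaffected by the tie rule.

Layer normalization standardises each frame across the 39 features,
$(x - \mu)/(\sigma + \epsilon)$ with population $\sigma$ and
$\epsilon = 10^{-8}$ guarding constant frames.

Sigma-Delta modulation converts each channel independently:
$$e[n] = x[n] - y[n-1],\quad s[n] = (1-\alpha)\,s[n-1] + e[n],\quad
q[n] = \mathbf{1}[s[n] \ge \theta],\quad y[n] = q[n].$$
With $\alpha = 0$ (the default, a pure first-order accumulator) the running
spike count tracks the integrated input: for constant $x \in [0, \theta]$
the long-run rate converges to $x/\theta$, and the running deficit
$|\sum_{k\le n}(x[k]-y[k])|$ is bounded by $\theta + \max|x|$. Negative
normalized excursions simply emit no spikes — that, plus the feedback, is
the sparsity mechanism. $\alpha \in (0,1)$ adds an integrator leak for
stability experiments.

**Choice of $\theta$.** The threshold is in units of feature standard
deviations because it acts on layer-normalized values. At $\theta = 1$ the
positive z-score mass fires roughly a quarter of all channel-steps, which is
not a sparse code. The default $\theta = 12$ requires about twelve
SD-units of accumulated evidence per spike, putting the modulator in the
sparse regime this encoder is meant to produce (about 5% activity on the
synthetic utterances, i.e. sparsity above 0.9) while leaving the classes
clearly separated in raster space. An optional per-channel min–max rescale
to $[0,1]$ is provided for unipolar experiments.

# Reservoir dynamics

Membrane dynamics follow
$\tau_m \dot V = -(V - V_{rest}) + R_m I_{syn}(t)$ with forward-Euler
integration at $dt = 0.1$ ms (configurable); crossing $V_{th}$ emits a spike
and clamps the neuron at $V_{reset}$ for the 2 ms refractory period, during
which input is ignored. Parameters: $\tau_m = 20$ ms, $V_{rest} = -65$ mV,
$V_{th} = -50$ mV, $V_{reset} = -70$ mV, $R_m = 1\,\mathrm{M\Omega}$.
The Euler solution under constant current agrees with the exact exponential
to within 1% at $dt = 0.01$ ms, and halving $dt$ changes the spike count of
a fixed run by well under 5% at $dt \le 0.1$ ms.

Each undirected graph edge becomes two directed synapses. Neurons are
labelled excitatory (80%) or inhibitory, and all outgoing synapses inherit
the label (Dale-consistent). The synaptic current is
$I_{syn} = g\, r_g\,(E_{syn} - V_{post})$ where $r_g$, the bound-receptor
fraction, obeys $\dot r_g = \alpha H (1 - r_g) - \beta r_g$ with
$\alpha, \beta = 2, 1\ \mathrm{ms^{-1}}$ (excitatory; 0.9, 0.1 inhibitory)
and reversal potentials 0 / −70 mV.

**The neurotransmitter gate.** $H$ is a logistic gate on the *delayed*
presynaptic potential, $H = 1/(1 + e^{-V_{pre}(t - \tau_{delay})/v_{scale}})$
with $v_{scale} = 5$ mV. Subthreshold LIF potentials are always far negative
(so $H \approx 0$); the gate opens only during the action potential, which a
point-neuron model does not represent explicitly. We therefore substitute a
+30 mV spike waveform for 1 ms after each presynaptic spike — the standard
receptor-kinetics treatment of transmitter release in point-neuron models.
This interpretation is flagged prominently because the gate's functional
form is the one genuinely underdetermined piece of the synapse model.

STDP: between pairings the weight decays exponentially
($\tau_{ex} = 3$ ms excitatory, $\tau_{in} = 5$ ms inhibitory); on a pairing
with $\Delta t = t_{pre} - t_{post}$ the weight gains
$w(\Delta t)\,g_{max}$ where $w = A_+ e^{\Delta t/\tau_+}$ for
$\Delta t < 0$ and $-A_- e^{-\Delta t/\tau_-}$ otherwise
($A_+ = 0.1$, $A_- = 0.105$, $\tau_\pm = 20$ ms, $g_{max} = 0.015$); the
inhibitory modulation uses $B_+ = 0.02$, $B_- = 0.03$ with opposite signs.
Weights are clipped to $[0, g_{max}]$ after every update. Pre-side pairings
are evaluated when the delayed spike *arrives* at the synapse. Conduction
delays are drawn once per synapse from a Poisson distribution with 10 ms
mean, clipped to $[0.1, 40]$ ms.

With a 3 ms decay constant, weights relax toward zero between the
$\ge 10$ ms-spaced spikes of this task, so recurrent currents are weak and
the reservoir acts mainly as a delayed, refractory-limited, plastic relay of
its input. That is a direct consequence of the stated plasticity constants,
and we keep it; the firing-separability analysis below shows the
representation is nevertheless strongly class-discriminative.

**Input conversion.** Each encoder spike is injected as a rectangular
current pulse into its mapped neuron. A pulse must cross the 15 mV gap from
rest within its width; from the post-spike reset potential the gap is
20 mV. With $\tau_m = 20$ ms and a 1 ms pulse this requires
$R_m I \ge 20/(1 - e^{-1/20}) \approx 410$ mV, so the default is 450 nA ×
1 ms: one input spike reliably elicits one reservoir spike even on
consecutive frames, and the input raster is relayed faithfully. (A 30 nA
pulse, for comparison, depolarises by only ~1.5 mV and never fires the
cell — too weak by two orders of magnitude to function as a spike
injection under these membrane constants.)

# Readout and learning

One output LIF neuron per class reads the reservoir raster binned at 1 ms;
its drive is `out_gain` × (weights · per-bin spike counts), with
`out_gain = 30` nA per unit weight per spike and weights clipped to
$[-20, 20]$. The desired trains are equal-count periodic templates: class
$k$ fires at 20 Hz starting at $150 + 5(k-1)$ ms. Two design points matter:

* **Warm-up offset.** The encoder's amplitude-envelope onset plus the
  Sigma-Delta integrator's charging leave the first ~130 ms of every episode
  without reservoir drive; template spikes placed there are unmatchable, so
  templates start at 150 ms.
* **Equal spike counts.** If template lengths differed across classes, a
  silent output would be systematically closer to the shortest template,
  biasing classification; all templates carry the same number of spikes.

The ReSuMe update for weight $j$ of an output neuron is evaluated per
episode in discrete-event form:
$$\Delta w_j = \sum_{t_d}\Big[e_H + \sum_{t^j_{in} \le t_d} A_+
  e^{-(t_d - t^j_{in})/\tau_+}\Big] -
  \sum_{t_a}\Big[e_H + \sum_{t^j_{in} \le t_a} A_+
  e^{-(t_a - t^j_{in})/\tau_+}\Big],$$
with $e_H = 0.25$ and the learning window reusing $A_+ = 0.1$,
$\tau_+ = 20$ ms. Missing desired spikes raise weights, spurious actual
spikes lower them, each gated by the synapse's recent input. The rule is
antisymmetric in (actual, desired) and zero when they coincide.

The raw deltas are large relative to the discrete firing threshold, so an
unscaled update rings around the equilibrium. The learning-rate defaults
were set accordingly: 0.3 for the single-neuron task (`resume_fit()`, one
episode per cycle) and 0.002 for the full readout (`train_readout()`, where
every one of the ~200 training presentations per cycle applies a delta).
Both values came from convergence studies across many seeds, not from a
single lucky run.

Reservoir plasticity is frozen across readout training: every presentation
restarts the reservoir from its stored initial state (STDP still acts
*within* each run), so per-utterance responses are deterministic and are
computed once and reused across the 240 cycles. This isolates readout
learning and is switchable.

Classification runs the reservoir and output layer and returns the class
whose output train is closest (van Rossum distance, $\tau = 20$ ms, computed
in closed form) to its *own* template, ties to the lowest class index. The
input channel→neuron map is drawn once per experiment from the experiment
seed and persisted with the model (`write_readout_model()` round-trips the
whole model, including the reservoir, as JSON).

# Firing and transmission analytics

Firing separability is tested with a one-way ANOVA: one group per stimulus
class, one observation per time bin of the summed population firing counts.
`firing_counts()` bins at 1 ms by default; the experiment-level analysis
(`run_speech_experiment()`) groups at 10 ms — the input frame grid — because
at 1 ms resolution nine of every ten bins are structurally empty for every
class and only dilute the F statistic. Zero within-group variance is
reported as a degenerate flag, never a silent infinite F.

Transmission structure uses three quantities on the (symmetrized, mean of
the two directed weights) synapse matrix: synaptic density (non-zero-weight
synapses per neuron), the weighted clustering coefficient
$$C_w = \frac{1}{N}\sum_i \frac{1}{s_i (D_i - 1)}
  \sum_{j \ne k} \frac{g_{ij} + g_{ik}}{2}\, a_{ij} a_{jk} a_{ki}$$
(ordered neighbour pairs, so uniform weights recover the binary clustering
coefficient exactly), and the weighted shortest path length with edge
lengths $1/g_{mn}$, averaged over ordered *reachable* pairs with the
reachable fraction reported (unreachable pairs are excluded rather than
imputed).

# Synthetic data

`gen_bold()` emulates parcellated resting-state signals as mixtures of a
global, a module-shared and an idiosyncratic AR(1) process with weights
chosen to hit target correlations exactly in expectation (within 0.6,
between 0.15, six modules of 15 regions, 200 volumes at TR = 1.5 s). At
$X_{th} = 0.3$ the resulting graph density falls at 0.16–0.19, inside the
biological band, and the graph is (almost always) connected — at
between-module coupling 0.10 the graph decomposed into disjoint modules,
which no empirical functional network does. The generator reproduces
correlation structure only: no hemodynamic response convolution, no
scanner noise spectrum, no spatial autocorrelation. Tests passing on it
show the graph pipeline is correct, not that the package reproduces any
particular cohort's networks.

`gen_audio_dataset()` synthesises 300–600 ms utterances at 12.5 kHz (the
native rate of the classic spoken-digit corpora): each class is a distinct
two-formant chirp pair with alternating sweep directions, a raised-cosine
envelope, and 5% white noise. The classes are far more cleanly separated
than real speakers' digits — accuracies on this set say the pipeline can
learn and discriminate, not that it would reach any particular accuracy on
real speech. All generators are pure functions of configuration and seed.

# Problem sizes and numerical choices

The bundled experiment (`run_speech_experiment()`, also what
`scripts/acceptance.R` runs) uses 10 classes × (20 train + 10 test), a
90-neuron reservoir from the synthetic FBN at $X_{th} = 0.3$, 240 training
cycles, $dt = 0.1$ ms, ~450 ms episodes — a scaled-down mirror of a
16-speaker spoken-digit protocol that completes in about a minute on one
core. Degenerate inputs are handled explicitly throughout: zero-variance
BOLD regions name the offending region, regular graphs yield an undefined
$\gamma$ flag, disconnected graphs either error (small-world index) or are
reduced to their largest component, empty weighted graphs yield an
undefined path length, and zero within-group variance flags the ANOVA.

# Known limitations

* The neurotransmitter-gate functional form is an interpretation (see
  above); alternatives (e.g. a depression time constant instead of the
  conduction delay in the gate argument) would change recurrent currents.
* Weight decay at 3 ms makes recurrent transmission weak at speech-like
  input rates; the reservoir's discriminative power here comes mostly from
  relay timing, refractoriness and the input map.
* Periodic phase-shifted templates are the simplest distinct-target scheme;
  data-driven templates could use the reservoir's own firing structure.
* The synthetic corpus is easier than real speech, and the synthetic BOLD
  has no hemodynamics; neither substitutes for the original data sources.
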