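#' Labeled spike set
#'
#' Bundles encoded utterances with their class labels, the training/test
#' currency of the LSM readout.
#'
#' @param rasters List of [spike_raster()] objects.
#' @param labels Vector of class labels, one per raster.
#' @return A tibble with list-column `raster` and column `label`, class
#'   `labeled_spike_set`.
#' @export
labeled_spike_set <- function(rasters, labels) {
  if (length(rasters) == 0) stop_input("empty spike set")
  if (length(rasters) != length(labels)) {
    stop_input("need one label per raster")
  }
  out <- tibble::tibble(raster = rasters, label = as.character(labels))
  class(out) <- c("labeled_spike_set", class(out))
  out
}

#' Desired output spike templates
#'
#' One periodic spike train per class: class k fires at `base_rate` Hz with a
#' phase offset of `(k-1) * phase_step` ms after `t_start`, making the
#' templates pairwise distinct while sharing rate and duration. These are the
#' S(t_d) targets the ReSuMe rule pulls each class's output neuron toward.
#'
#' @param classes Vector of class labels.
#' @param duration Episode length, ms.
#' @param base_rate Template firing rate, Hz (default 20).
#' @param phase_step Per-class phase offset, ms (default 5).
#' @param t_start First spike time of class 1, ms. The default of 150 ms
#'   leaves the encoder/reservoir warm-up period (amplitude onset plus
#'   Sigma-Delta integrator charging) free of target spikes, since no
#'   reservoir drive exists there to match them.
#' @return Named list of spike-time vectors (ms), deterministic.
#' @export
make_templates <- function(classes, duration, base_rate = 20,
                           phase_step = 5, t_start = 150) {
  assert_scalar_number(duration, "duration", lower = 1e-9)
  period <- 1000 / base_rate
  # same spike count for every class: a silent response is then equidistant
  # from all templates instead of favouring the shortest one
  max_offset <- t_start + (length(classes) - 1) * phase_step
  n_spk <- floor((duration - max_offset) / period) + 1
  out <- lapply(seq_along(classes), function(k) {
    t_start + (k - 1) * phase_step + period * (seq_len(n_spk) - 1)
  })
  names(out) <- as.character(classes)
  if (any(lengths(out) < 2)) {
    stop_input("`base_rate`/`duration` must yield at least 2 spikes per template")
  }
  key <- vapply(out, paste, character(1), collapse = ",")
  if (anyDuplicated(key)) stop_input("parameters yield identical templates")
  out
}

#' van Rossum distance between two spike trains
#'
#' Distance between trains filtered with a causal exponential kernel of time
#' constant `tau`; computed in closed form over the spike times.
#'
#' @param a,b Spike-time vectors, ms.
#' @param tau Kernel time constant, ms (default 20).
#' @return Non-negative scalar; 0 iff the trains are identical.
#' @export
van_rossum_distance <- function(a, b, tau = 20) {
  cross <- function(x, y) {
    if (length(x) == 0 || length(y) == 0) return(0)
    sum(exp(-abs(outer(x, y, "-")) / tau))
  }
  d2 <- 0.5 * (cross(a, a) + cross(b, b) - 2 * cross(a, b))
  sqrt(max(d2, 0))
}

# ReSuMe "sum over output spikes" term: for each output spike time t, the
# anti-Hebbian constant plus the causal STDP window over input spikes at or
# before t.
resume_term <- function(out_times, in_times, e_h, a_plus, tau_plus) {
  if (length(out_times) == 0) return(0)
  total <- length(out_times) * e_h
  if (length(in_times) > 0) {
    lag <- outer(out_times, in_times, "-")
    total <- total + a_plus * sum(exp(-lag / tau_plus)[lag >= 0])
  }
  total
}

#' One ReSuMe weight update
#'
#' Discrete-event evaluation of the remote supervised rule: the weight change
#' is the difference between the desired-train and actual-train terms,
#' \deqn{\Delta w = \sum_{t_d}\Big[e_H + \sum_{t_{in} \le t_d} A_+
#'   e^{-(t_d - t_{in})/\tau_+}\Big] - \sum_{t_a}\Big[\cdots\Big],}
#' so missing desired spikes raise the weight and spurious actual spikes
#' lower it, each modulated by how much recent input the synapse carried.
#'
#' @param w Current weight (returned unchanged; the delta is the result).
#' @param s_in Input spike times, ms.
#' @param s_a Actual output spike times, ms.
#' @param s_d Desired output spike times, ms.
#' @param e_h Anti-Hebbian coefficient (default 0.25).
#' @param a_plus,tau_plus Learning-window amplitude and time constant
#'   (shared with the STDP parameters; defaults 0.1 and 20 ms).
#' @param learning_rate Scale applied to the computed delta.
#' @return The weight delta.
#' @export
resume_step <- function(w, s_in, s_a, s_d, e_h = 0.25, a_plus = 0.1,
                        tau_plus = 20, learning_rate = 1) {
  learning_rate *
    (resume_term(s_d, s_in, e_h, a_plus, tau_plus) -
       resume_term(s_a, s_in, e_h, a_plus, tau_plus))
}

#' Fit a single ReSuMe readout neuron to input spike trains
#'
#' The elementary supervised-learning task the full readout is built from:
#' one output LIF neuron receives weighted pulses from `n` input spike
#' trains, and its weight vector is trained over repeated cycles of
#' (simulate response, apply the ReSuMe delta of [resume_step()]) so that its
#' actual spike train approaches the `desired` one.
#'
#' @param input_trains List of input spike-time vectors (ms), or a binned
#'   spike-count matrix (inputs x ms bins).
#' @param desired Desired output spike times, ms.
#' @param duration Episode length, ms; defaults to cover all spikes.
#' @param cycles Training cycles (default 240).
#' @param nparams Output neuron parameters.
#' @param e_h,a_plus,tau_plus ReSuMe rule constants.
#' @param learning_rate Update scale (default 0.3).
#' @param out_gain Drive per unit weight per input spike, nA.
#' @param w_max Weight cap.
#' @param tau_vr van Rossum constant for the convergence history, ms.
#' @param eval_every Record the distance every this many cycles.
#' @return List with `weights`, `history` (tibble: cycle, vr_distance),
#'   `actual` (final output spike times, ms).
#' @export
resume_fit <- function(input_trains, desired, duration = NULL, cycles = 240,
                       nparams = neuron_params(), e_h = 0.25, a_plus = 0.1,
                       tau_plus = 20, learning_rate = 0.3, out_gain = 30,
                       w_max = 5, tau_vr = 20, eval_every = 40) {
  if (is.matrix(input_trains)) {
    b <- input_trains
  } else {
    duration <- duration %||% ceiling(max(c(unlist(input_trains), desired)))
    b <- matrix(0, length(input_trains), duration)
    for (j in seq_along(input_trains)) {
      bins <- pmin(pmax(ceiling(input_trains[[j]]), 1), duration)
      for (t in bins) b[j, t] <- b[j, t] + 1
    }
  }
  x <- filter_trace(b, exp(-1 / tau_plus))
  d_bins <- pmin(pmax(ceiling(desired), 1), ncol(b))
  d_part <- length(desired) * e_h + a_plus * rowSums(x[, d_bins, drop = FALSE])
  w <- numeric(nrow(b))
  respond <- function(w) {
    which(lif_response_cpp(out_gain * matrix(w %*% b, 1), 1, nparams)[1, ] == 1L)
  }
  history <- list()
  for (cyc in seq_len(cycles)) {
    ta <- respond(w)
    a_part <- length(ta) * e_h +
      a_plus * (if (length(ta)) rowSums(x[, ta, drop = FALSE]) else 0)
    w <- pmin(pmax(w + learning_rate * (d_part - a_part), -w_max), w_max)
    if (cyc == 1 || cyc %% eval_every == 0 || cyc == cycles) {
      history[[length(history) + 1]] <- tibble::tibble(
        cycle = cyc,
        vr_distance = van_rossum_distance(respond(w), desired, tau_vr))
    }
  }
  list(weights = w, history = dplyr::bind_rows(history), actual = respond(w))
}

# bin a reservoir raster (dt ms) into counts at `bin` ms resolution
bin_raster <- function(raster, raster_dt_ms, bin_ms) {
  spb <- max(1L, round(bin_ms / raster_dt_ms))
  n_bins <- ncol(raster) %/% spb
  m <- raster[, seq_len(n_bins * spb), drop = FALSE]
  arr <- array(as.numeric(m), dim = c(nrow(m), spb, n_bins))
  colSums(aperm(arr, c(2, 1, 3)))
}

# exponentially filtered spike counts: X[, t] = lambda * X[, t-1] + B[, t]
filter_trace <- function(b, lambda) {
  x <- b
  if (ncol(b) > 1) {
    for (t in 2:ncol(b)) x[, t] <- lambda * x[, t - 1] + b[, t]
  }
  x
}

#' Train the LSM readout with ReSuMe
#'
#' For every training cycle and utterance, the reservoir response is obtained
#' (reservoir plasticity is frozen across training: every presentation starts
#' from the same initial reservoir, so per-utterance responses are computed
#' once and reused), the output LIF neurons -- one per class -- are driven
#' through the current weights, and each output neuron's weights receive a
#' ReSuMe update with its class template as the desired train for matching
#' utterances and an empty desired train otherwise.
#'
#' @param train_set A [labeled_spike_set()].
#' @param reservoir A `reservoir_state` from [initialize_reservoir()].
#' @param cycles Training cycles (passes over the set), default 240.
#' @param seed Integer seed (controls the input channel-to-neuron map).
#' @param templates Optional named list of desired trains; defaults to
#'   [make_templates()] over the episode duration.
#' @param e_h Anti-Hebbian coefficient (default 0.25).
#' @param learning_rate Scale on each weight delta (default 0.002). Every
#'   utterance presentation applies one delta, so the effective per-cycle
#'   step grows with the training-set size; the raw ReSuMe terms overshoot
#'   the discrete-firing equilibrium and oscillate if unscaled. The
#'   single-episode task ([resume_fit()]) uses a larger default.
#' @param out_gain Output drive per unit weight per reservoir spike, nA.
#' @param w_max Readout weight cap (weights clipped to \[-w_max, w_max\]).
#' @param readout_bin Output-layer integration step, ms.
#' @param tau_vr van Rossum time constant for monitoring/classification, ms.
#' @param base_rate,phase_step Template parameters when `templates` is NULL.
#' @param eval_every Record the mean own-class van Rossum distance every this
#'   many cycles.
#' @param input_amplitude,pulse_width,dt Passed to [run_reservoir()].
#' @param run_plasticity Apply STDP inside each reservoir run (default TRUE;
#'   the run always starts from the stored initial state either way).
#' @return A `readout_model`: weights (reservoir x classes), templates,
#'   input map, the initial reservoir, parameters and a convergence history
#'   tibble (`cycle`, `mean_vr_distance`).
#' @export
train_readout <- function(train_set, reservoir, cycles = 240, seed = 1,
                          templates = NULL, e_h = 0.25, learning_rate = 0.002,
                          out_gain = 30, w_max = 20, readout_bin = 1,
                          tau_vr = 20, base_rate = 20, phase_step = 5,
                          eval_every = 40, input_amplitude = 450,
                          pulse_width = 1, dt = 0.1, run_plasticity = TRUE) {
  stopifnot(inherits(train_set, "labeled_spike_set"))
  if (cycles < 1) stop_input("`cycles` must be >= 1")
  n_res <- length(reservoir$v)
  n_ch <- nrow(train_set$raster[[1]])
  a_plus <- reservoir$sparams$a_plus
  tau_plus <- reservoir$sparams$tau_plus
  input_map <- with_seed(seed, sample.int(n_res, n_ch))
  classes <- sort(unique(train_set$label))

  duration <- max(vapply(train_set$raster, function(r) {
    ncol(r) * attr(r, "dt") * 1000
  }, numeric(1)))
  templates <- templates %||%
    make_templates(classes, duration, base_rate, phase_step)

  # one reservoir pass per utterance (responses are reused across cycles)
  lambda <- exp(-readout_bin / tau_plus)
  cache <- lapply(seq_len(nrow(train_set)), function(i) {
    sim <- run_reservoir(reservoir, train_set$raster[[i]], input_map,
                         input_amplitude = input_amplitude,
                         pulse_width = pulse_width,
                         duration = duration, dt = dt,
                         plasticity = run_plasticity)
    b <- bin_raster(unclass(sim$raster), dt, readout_bin)
    x <- filter_trace(b, lambda)
    # desired-train term of the ReSuMe rule, per class output neuron
    d_part <- vapply(classes, function(cl) {
      if (train_set$label[i] != cl) return(numeric(n_res))
      td <- templates[[cl]]
      bins <- pmin(pmax(ceiling(td / readout_bin), 1), ncol(x))
      length(td) * e_h + a_plus * rowSums(x[, bins, drop = FALSE])
    }, numeric(n_res))
    list(b = b, x = x, d_part = d_part, label = train_set$label[i])
  })

  n_bins <- ncol(cache[[1]]$b)
  w <- matrix(0, n_res, length(classes), dimnames = list(NULL, classes))
  history <- list()
  for (cyc in seq_len(cycles)) {
    track <- cyc == 1 || cyc %% eval_every == 0 || cyc == cycles
    vr <- numeric(0)
    for (u in cache) {
      drive <- out_gain * crossprod(w, u$b)
      out_spikes <- lif_response_cpp(drive, readout_bin, reservoir$nparams)
      for (o in seq_along(classes)) {
        ta <- which(out_spikes[o, ] == 1L)
        a_part <- length(ta) * e_h +
          a_plus * (if (length(ta)) rowSums(u$x[, ta, drop = FALSE])
                    else numeric(n_res))
        w[, o] <- w[, o] + learning_rate * (u$d_part[, o] - a_part)
      }
      w[w > w_max] <- w_max
      w[w < -w_max] <- -w_max
      if (track) {
        o <- match(u$label, classes)
        ta_own <- which(lif_response_cpp(out_gain * crossprod(w, u$b),
                                         readout_bin,
                                         reservoir$nparams)[o, ] == 1L)
        vr <- c(vr, van_rossum_distance(ta_own * readout_bin,
                                        templates[[u$label]], tau_vr))
      }
    }
    if (track) {
      history[[length(history) + 1]] <-
        tibble::tibble(cycle = cyc, mean_vr_distance = mean(vr))
    }
  }

  structure(list(
    weights = w, templates = templates, classes = classes,
    input_map = input_map, reservoir = reservoir,
    params = list(e_h = e_h, a_plus = a_plus, tau_plus = tau_plus,
                  learning_rate = learning_rate, out_gain = out_gain,
                  w_max = w_max, readout_bin = readout_bin, tau_vr = tau_vr,
                  duration = duration, cycles = cycles, seed = seed,
                  input_amplitude = input_amplitude,
                  pulse_width = pulse_width, dt = dt,
                  run_plasticity = run_plasticity),
    history = dplyr::bind_rows(history)
  ), class = "readout_model")
}

#' @export
print.readout_model <- function(x, ...) {
  cat(sprintf("<readout_model> %d reservoir neurons -> %d classes, %d cycles\n",
              nrow(x$weights), ncol(x$weights), x$params$cycles))
  if (nrow(x$history)) {
    cat(sprintf("  own-class van Rossum distance: %.3f (cycle 1) -> %.3f (cycle %d)\n",
                x$history$mean_vr_distance[1],
                utils::tail(x$history$mean_vr_distance, 1),
                utils::tail(x$history$cycle, 1)))
  }
  invisible(x)
}

# output-layer spike times (ms) per class for one encoded utterance
readout_response <- function(model, utter_raster) {
  p <- model$params
  sim <- run_reservoir(model$reservoir, utter_raster, model$input_map,
                       input_amplitude = p$input_amplitude,
                       pulse_width = p$pulse_width,
                       duration = p$duration, dt = p$dt,
                       plasticity = p$run_plasticity)
  b <- bin_raster(unclass(sim$raster), p$dt, p$readout_bin)
  drive <- p$out_gain * crossprod(model$weights, b)
  out_spikes <- lif_response_cpp(drive, p$readout_bin, model$reservoir$nparams)
  lapply(seq_along(model$classes),
         function(o) which(out_spikes[o, ] == 1L) * p$readout_bin)
}

#' Classify an encoded utterance
#'
#' Runs the reservoir and the trained output layer, then returns the class
#' whose output neuron's actual spike train is closest (van Rossum distance)
#' to that class's own template. Ties break to the lowest class index.
#'
#' @param model A `readout_model` from [train_readout()].
#' @param utterance A 39-channel [spike_raster()].
#' @return The predicted class label (character scalar).
#' @export
classify <- function(model, utterance) {
  stopifnot(inherits(model, "readout_model"))
  actual <- readout_response(model, utterance)
  d <- vapply(seq_along(model$classes), function(o) {
    van_rossum_distance(actual[[o]], model$templates[[model$classes[o]]],
                        model$params$tau_vr)
  }, numeric(1))
  model$classes[which.min(d)]
}

#' Evaluate a readout model on a labeled test set
#'
#' @param model A `readout_model`.
#' @param test_set A [labeled_spike_set()].
#' @return A tibble with `label`, `predicted`, `correct`; overall accuracy in
#'   attribute `accuracy`.
#' @export
evaluate_readout <- function(model, test_set) {
  stopifnot(inherits(test_set, "labeled_spike_set"))
  pred <- vapply(test_set$raster, function(r) classify(model, r), character(1))
  out <- tibble::tibble(label = test_set$label, predicted = pred,
                        correct = pred == test_set$label)
  attr(out, "accuracy") <- mean(out$correct)
  out
}
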