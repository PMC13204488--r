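# unit-variance stationary AR(1) series
ar1_series <- function(n, phi) {
  innov_sd <- sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  for (t in 2:n) x[t] <- phi * x[t - 1] + innov_sd * stats::rnorm(1)
  x
}

#' Synthetic modular BOLD time series
#'
#' Emulates parcellated resting-state fMRI signals with a block (modular)
#' correlation structure: each region mixes a global signal, its module's
#' shared signal and idiosyncratic noise, all unit-variance AR(1) processes,
#' with mixing weights chosen so that the expected Pearson correlation is
#' `r_within` inside a module and `r_between` across modules. Defaults mirror
#' a typical single-session scan: 90 regions, 200 volumes at TR = 1.5 s, six
#' modules, correlations 0.6 / 0.15 -- chosen so that thresholding |R| at 0.3
#' lands the graph density inside the biological brain-network range
#' (3.6-39.3%). No hemodynamic response model is applied; the generator
#' targets correlation structure, not hemodynamics.
#'
#' @param n_regions Number of regions (default 90).
#' @param n_samples Number of volumes (default 200).
#' @param sampling_interval TR, seconds (default 1.5).
#' @param n_modules Number of modules (default 6).
#' @param r_within,r_between Target correlations (need
#'   `0 <= r_between < r_within <= 1`).
#' @param ar_coefficient Temporal smoothness of every latent process.
#' @param n_subjects Number of independent matrices to generate.
#' @param seed Integer seed; output is a pure function of config + seed.
#' @return A list of [bold_matrix()] objects, length `n_subjects`.
#' @export
gen_bold <- function(n_regions = 90, n_samples = 200, sampling_interval = 1.5,
                     n_modules = 6, r_within = 0.6, r_between = 0.15,
                     ar_coefficient = 0.3, n_subjects = 1, seed = 20260426) {
  if (!(r_between >= 0 && r_between < r_within && r_within <= 1)) {
    stop_input("need 0 <= r_between < r_within <= 1")
  }
  if (n_modules > n_regions) stop_input("more modules than regions")
  module <- sort(rep_len(seq_len(n_modules), n_regions))
  w_glob <- sqrt(r_between)
  w_mod <- sqrt(r_within - r_between)
  w_noise <- sqrt(1 - r_within)
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      glob <- ar1_series(n_samples, ar_coefficient)
      mods <- replicate(n_modules, ar1_series(n_samples, ar_coefficient))
      vals <- t(vapply(seq_len(n_regions), function(i) {
        w_glob * glob + w_mod * mods[, module[i]] +
          w_noise * ar1_series(n_samples, ar_coefficient)
      }, numeric(n_samples)))
      bold_matrix(vals,
                  region_labels = sprintf("M%d_R%d", module, seq_len(n_regions)),
                  sampling_interval = sampling_interval)
    })
  })
}

# one synthetic utterance: two formant chirps with class-specific start/end
# frequencies, a raised-cosine envelope and additive white noise
synth_utterance <- function(f1, f2, duration_s, sample_rate, noise_level) {
  n <- round(duration_s * sample_rate)
  tt <- seq_len(n) / sample_rate
  sweep_phase <- function(f) {
    freq <- seq(f[1], f[2], length.out = n)
    2 * pi * cumsum(freq) / sample_rate
  }
  env <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))
  x <- env * (0.6 * sin(sweep_phase(f1)) + 0.4 * sin(sweep_phase(f2))) +
    noise_level * stats::rnorm(n)
  waveform(x / max(abs(x)), sample_rate)
}

#' Synthetic class-distinct spoken-digit-like dataset
#'
#' Generates short utterances (default 300-600 ms at 12.5 kHz, matching the
#' native rate of classic spoken-digit corpora) for `n_classes` classes. Each
#' class has a distinct two-formant trajectory: class-specific start and end
#' frequencies for both formants, with alternating sweep directions, plus a
#' raised-cosine amplitude envelope and white noise. Durations vary uniformly
#' within the range, and the train/test split is reproducible from the seed.
#'
#' @param n_classes Number of classes (default 10).
#' @param n_train,n_test Utterances per class in each split.
#' @param sample_rate Hz (default 12500).
#' @param duration_ms Duration range, ms (default 300-600).
#' @param noise_level Additive white-noise standard deviation relative to
#'   unit signal amplitude (default 0.05).
#' @param seed Integer seed; same seed regenerates identical waveforms.
#' @return A tibble with columns `class` (character), `split`
#'   ("train"/"test"), `waveform` (list of [waveform()]).
#' @export
gen_audio_dataset <- function(n_classes = 10, n_train = 20, n_test = 10,
                              sample_rate = 12500, duration_ms = c(300, 600),
                              noise_level = 0.05, seed = 20260426) {
  if (n_classes < 2) stop_input("need at least 2 classes")
  k <- seq_len(n_classes)
  # distinct formant trajectories: starts ramp up with class, direction of
  # the sweep alternates so neighbouring classes differ in dynamics too
  dir1 <- ifelse(k %% 2 == 0, 1, -1)
  f1_start <- 250 + 55 * (k - 1)
  f1_end <- f1_start + dir1 * (120 + 15 * (k - 1))
  f2_start <- 1000 + 180 * (k - 1)
  f2_end <- f2_start - dir1 * (250 + 20 * (k - 1))
  if (anyDuplicated(cbind(f1_start, f1_end, f2_start, f2_end))) {
    stop_input("degenerate class trajectories")
  }
  with_seed(seed, {
    rows <- list()
    for (cl in k) {
      for (i in seq_len(n_train + n_test)) {
        dur <- stats::runif(1, duration_ms[1], duration_ms[2]) / 1000
        w <- synth_utterance(c(f1_start[cl], f1_end[cl]),
                             c(f2_start[cl], f2_end[cl]),
                             dur, sample_rate, noise_level)
        rows[[length(rows) + 1]] <- tibble::tibble(
          class = sprintf("c%02d", cl),
          split = if (i <= n_train) "train" else "test",
          waveform = list(w)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Canonical toy fixtures with precomputed expected values
#'
#' Small graphs, feature columns and encoder inputs with hand-derived
#' expectations, used throughout the test suite: the uniform-weight triangle
#' (weighted clustering coefficient 1), star and complete graphs, the ring of
#' six nodes (density 6/15 = 0.4), a 3 x 5 BOLD matrix, the `[1, 2, 3]`
#' normalization column (population z-scores \eqn{\pm 1.2247, 0}) and the
#' constant-0.5 Sigma-Delta channel (50 spikes per 100 steps at theta = 1).
#'
#' @return A named list of fixtures, each a list with the object and its
#'   `expected` value(s).
#' @export
gen_toy_fixtures <- function() {
  ring6 <- topology(6, cbind(1:6, c(2:6, 1)))
  list(
    triangle = list(
      graph = weighted_graph_view(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)),
      expected = list(weighted_cc = 1)
    ),
    star5 = list(
      graph = {
        w <- matrix(0, 5, 5); w[1, 2:5] <- w[2:5, 1] <- 1
        weighted_graph_view(w)
      },
      expected = list(weighted_cc = 0)
    ),
    complete5 = list(
      graph = topology(5, t(utils::combn(5, 2))),
      expected = list(density = 1)
    ),
    ring6 = list(
      graph = ring6,
      expected = list(density = 0.4)
    ),
    bold3x5 = list(
      bold = bold_matrix(matrix(c(1, 2, 3, 4, 5,
                                  2, 1, 4, 3, 6,
                                  5, 4, 3, 2, 1), 3, byrow = TRUE),
                         sampling_interval = 1.5),
      expected = list(r_13 = -1)  # row 3 is a decreasing ramp of row 1
    ),
    norm_column = list(
      column = c(1, 2, 3),
      expected = list(normalized = c(-sqrt(3 / 2), 0, sqrt(3 / 2)))
    ),
    sigma_delta_half = list(
      input = matrix(0.5, 1, 100),
      expected = list(n_spikes = 50)
    )
  )
}
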