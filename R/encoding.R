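#' Encoder configuration
#'
#' Bundles every tunable of the waveform-to-spikes pipeline. Frame defaults
#' are the common speech front-end choices: 25 ms Hamming windows advanced by
#' 10 ms, pre-emphasis 0.97, 26 Mel filters, 13 cepstra with c0 retained.
#' `theta` is the Sigma-Delta quantizer threshold applied to layer-normalized
#' features (so it is in standard-deviation units); the default of 12 puts
#' the modulator in the sparse regime this encoder targets (roughly 5%
#' channel activity on speech-like input) while keeping classes separable.
#' `alpha` is an optional integrator leak in \[0, 1), 0 meaning a pure
#' first-order accumulator.
#'
#' @param frame_length,frame_step Analysis window length and hop, seconds.
#' @param n_mel Number of Mel filters.
#' @param context_n Context half-width N of the central-difference derivative
#'   estimator used for the delta features (default 2).
#' @param pre_emphasis Pre-emphasis coefficient.
#' @param target_frames Common frame count utterances are warped to before
#'   normalization; `NULL` skips alignment.
#' @param epsilon Layer-normalization guard against zero variance.
#' @param theta,alpha,initial_state Sigma-Delta modulator parameters.
#' @param rescale If `TRUE`, min-max rescale each feature channel to \[0, 1\]
#'   before modulation (by default negative excursions simply emit no spikes,
#'   which is the sparsity mechanism).
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(frame_length = 0.025, frame_step = 0.010,
                           n_mel = 26, context_n = 2, pre_emphasis = 0.97,
                           target_frames = NULL, epsilon = 1e-8,
                           theta = 12, alpha = 0, initial_state = 0,
                           rescale = FALSE) {
  assert_scalar_number(theta, "theta", lower = 1e-12)
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1 - 1e-12)
  structure(as.list(environment()), class = "encoder_config")
}

# triangular Mel filterbank, n_mel x (nfft/2 + 1)
mel_filterbank <- function(n_mel, nfft, sample_rate) {
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- mel2hz(seq(hz2mel(0), hz2mel(sample_rate / 2), length.out = n_mel + 2))
  bins <- floor((nfft + 1) * pts / sample_rate)
  fb <- matrix(0, n_mel, nfft / 2 + 1)
  for (m in seq_len(n_mel)) {
    lo <- bins[m]; ce <- bins[m + 1]; hi <- bins[m + 2]
    for (k in seq(lo, hi)) {
      if (k < 0 || k > nfft / 2) next
      w <- if (k < ce) (k - lo) / max(1, ce - lo) else (hi - k) / max(1, hi - ce)
      fb[m, k + 1] <- max(0, w)
    }
  }
  fb
}

# orthonormal DCT-II basis, n_cep x n_mel
dct_basis <- function(n_cep, n_mel) {
  b <- matrix(0, n_cep, n_mel)
  for (k in 0:(n_cep - 1)) {
    b[k + 1, ] <- cos(pi * k * (seq_len(n_mel) - 0.5) / n_mel) *
      sqrt((if (k == 0) 1 else 2) / n_mel)
  }
  b
}

# central-difference dynamic features with replicate padding (Eq.-style
# estimator: delta_t = sum_n n (c_{t+n} - c_{t-n}) / (2 sum_n n^2))
delta_features <- function(x, n) {
  tt <- ncol(x)
  idx <- function(i) pmin(pmax(i, 1), tt)
  denom <- 2 * sum((1:n)^2)
  out <- matrix(0, nrow(x), tt)
  for (k in 1:n) {
    out <- out + k * (x[, idx(seq_len(tt) + k), drop = FALSE] -
                        x[, idx(seq_len(tt) - k), drop = FALSE])
  }
  out / denom
}

#' Enhanced MFCC feature extraction
#'
#' Standard MFCC front end (pre-emphasis, framing, Hamming window, FFT
#' magnitude, Mel filterbank, log, DCT) augmented with first- and second-order
#' dynamic features from a central-difference derivative estimator, giving a
#' 39-dimensional vector per frame (13 static + 13 delta + 13 delta-delta).
#' Edge frames are handled by replicating the first/last frame.
#'
#' @param w A [waveform()].
#' @param frame_length,frame_step Window length and hop in seconds.
#' @param n_mel Number of Mel filters.
#' @param context_n Context half-width of the derivative estimator.
#' @param pre_emphasis Pre-emphasis coefficient.
#' @return A [feature_matrix()] (39 x frames).
#' @export
extract_features <- function(w, frame_length = 0.025, frame_step = 0.010,
                             n_mel = 26, context_n = 2, pre_emphasis = 0.97) {
  stopifnot(inherits(w, "waveform"))
  if (context_n < 1) stop_input("`context_n` must be >= 1")
  if (frame_length <= 0 || frame_step <= 0) {
    stop_input("frame parameters must be positive")
  }
  fs <- w$sample_rate
  flen <- round(frame_length * fs)
  fstep <- round(frame_step * fs)
  x <- w$samples
  if (length(x) < flen) stop_input("waveform shorter than one analysis frame")
  x <- c(x[1], x[-1] - pre_emphasis * x[-length(x)])
  n_frames <- floor((length(x) - flen) / fstep) + 1
  nfft <- 2^ceiling(log2(flen))
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(flen - 1)) / (flen - 1))
  fb <- mel_filterbank(n_mel, nfft, fs)
  dct <- dct_basis(13, n_mel)
  static <- matrix(0, 13, n_frames)
  for (f in seq_len(n_frames)) {
    seg <- x[((f - 1) * fstep + 1):((f - 1) * fstep + flen)] * win
    spec <- Mod(stats::fft(c(seg, rep(0, nfft - flen))))[1:(nfft / 2 + 1)]
    mel <- fb %*% spec^2
    static[, f] <- dct %*% log(pmax(mel, 1e-12))
  }
  d1 <- delta_features(static, context_n)
  d2 <- delta_features(d1, context_n)
  feature_matrix(rbind(static, d1, d2), frame_step)
}

# pairwise local distance matrix between frame sequences (columns)
frame_dist <- function(a, b, metric) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  if (metric == "euclidean") {
    na <- ncol(a); nb <- ncol(b)
    m <- matrix(0, na, nb)
    for (j in seq_len(nb)) m[, j] <- sqrt(colSums((a - b[, j])^2))
    m
  } else if (metric == "manhattan") {
    na <- ncol(a); nb <- ncol(b)
    m <- matrix(0, na, nb)
    for (j in seq_len(nb)) m[, j] <- colSums(abs(a - b[, j]))
    m
  } else {
    stop_input("unknown local distance: ", metric)
  }
}

#' Dynamic time warping between two frame sequences
#'
#' Minimum-cost monotone alignment with the classic three-predecessor
#' recurrence \eqn{D(i,j) = d(i,j) + \min\{D(i-1,j), D(i,j-1), D(i-1,j-1)\}}
#' and no slope weighting. Sequences are matrices with one column per frame
#' (plain vectors are treated as one-dimensional frames).
#'
#' @param seq_a,seq_b Frame sequences.
#' @param local_distance `"euclidean"` (default) or `"manhattan"`.
#' @return A list with `distance` (the accumulated cost at the terminal cell)
#'   and `path`, a two-column matrix of aligned (i, j) index pairs from (1, 1)
#'   to (|a|, |b|).
#' @export
dtw_warp <- function(seq_a, seq_b, local_distance = "euclidean") {
  d <- frame_dist(seq_a, seq_b, local_distance)
  n <- nrow(d); m <- ncol(d)
  if (n == 0 || m == 0) stop_input("sequences must be non-empty")
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- d[i, j] + min(D[i, j + 1], D[i + 1, j], D[i, j])
    }
  }
  # backtrack, preferring the diagonal on ties
  path <- matrix(0L, n + m, 2)
  i <- n; j <- m; row <- 1L
  path[row, ] <- c(i, j)
  while (i > 1 || j > 1) {
    prev <- c(D[i, j], D[i, j + 1], D[i + 1, j])  # diag, up, left
    pick <- which.min(prev)
    if (pick == 1) { i <- i - 1; j <- j - 1 }
    else if (pick == 2) i <- i - 1
    else j <- j - 1
    row <- row + 1L
    path[row, ] <- c(i, j)
  }
  list(distance = D[n + 1, m + 1],
       path = path[rev(seq_len(row)), , drop = FALSE])
}

#' Warp a feature matrix to a fixed number of frames
#'
#' Aligns the frame axis to `target_frames` columns with [dtw_warp()] against
#' a reference sequence. The default reference is the uniform time-stretch of
#' the input itself (columns linearly interpolated onto a uniform grid of the
#' target length), so alignment reduces to a smooth stretch unless an explicit
#' template is supplied. Output column j is the mean of all source frames the
#' path maps to j.
#'
#' @param f A [feature_matrix()].
#' @param target_frames Desired frame count.
#' @param reference Optional reference `feature_matrix` with `target_frames`
#'   columns.
#' @return A [feature_matrix()] with `target_frames` columns.
#' @export
align_to_length <- function(f, target_frames, reference = NULL) {
  stopifnot(inherits(f, "feature_matrix"))
  target_frames <- as.integer(target_frames)
  if (target_frames < 1) stop_input("`target_frames` must be >= 1")
  tt <- ncol(f)
  if (is.null(reference)) {
    grid <- seq(1, tt, length.out = target_frames)
    lo <- floor(grid); hi <- ceiling(grid); wt <- grid - lo
    reference <- unclass(f)[, lo, drop = FALSE] * (1 - rep(wt, each = nrow(f))) +
      unclass(f)[, hi, drop = FALSE] * rep(wt, each = nrow(f))
  } else {
    if (ncol(reference) != target_frames) {
      stop_input("`reference` must have `target_frames` columns")
    }
    reference <- unclass(reference)
  }
  path <- dtw_warp(unclass(f), reference)$path
  out <- matrix(0, nrow(f), target_frames)
  for (j in seq_len(target_frames)) {
    src <- path[path[, 2] == j, 1]
    out[, j] <- rowMeans(unclass(f)[, src, drop = FALSE])
  }
  feature_matrix(out, attr(f, "frame_step"))
}

#' Layer normalization of a feature matrix
#'
#' Per frame (column), subtracts the mean and divides by the population
#' standard deviation of the 39 features plus `epsilon`:
#' \eqn{x' = (x - \mu)/(\sigma + \epsilon)}.
#'
#' @param f A [feature_matrix()].
#' @param epsilon Guard constant against zero variance.
#' @return A normalized [feature_matrix()].
#' @export
normalize_features <- function(f, epsilon = 1e-8) {
  stopifnot(inherits(f, "feature_matrix"))
  v <- unclass(f)
  mu <- colMeans(v)
  sigma <- sqrt(colMeans(sweep(v, 2, mu)^2))
  feature_matrix(sweep(sweep(v, 2, mu), 2, sigma + epsilon, "/"),
                 attr(f, "frame_step"))
}

#' Sigma-Delta spike encoding
#'
#' Converts each feature channel independently into a binary spike train by
#' integrate-quantize-feedback modulation:
#' \deqn{e[n] = x[n] - y[n-1];\quad s[n] = (1-\alpha)s[n-1] + e[n];}
#' \deqn{q[n] = 1 \iff s[n] \ge \theta;\quad y[n] = q[n],}
#' with \eqn{s[0]} the configured initial state and \eqn{y[0] = 0}. The
#' running mean of the output tracks the input, so slowly varying or negative
#' stretches emit few or no spikes -- this is the sparsity mechanism.
#'
#' @param f A [feature_matrix()] (or plain numeric matrix, channels x steps).
#' @param config An [encoder_config()]; only `theta`, `alpha`,
#'   `initial_state` and `rescale` are used.
#' @return A [spike_raster()], one timestep per frame.
#' @export
sigma_delta_encode <- function(f, config = encoder_config()) {
  v <- unclass(f)
  if (!all(is.finite(v))) stop_input("features must be finite")
  if (isTRUE(config$rescale)) {
    rng <- apply(v, 1, range)
    span <- pmax(rng[2, ] - rng[1, ], 1e-12)
    v <- (v - rng[1, ]) / span
  }
  n_ch <- nrow(v); n_t <- ncol(v)
  s <- rep(config$initial_state, n_ch)
  y <- numeric(n_ch)
  q <- matrix(0L, n_ch, n_t)
  for (t in seq_len(n_t)) {
    s <- (1 - config$alpha) * s + (v[, t] - y)
    fire <- s >= config$theta
    q[fire, t] <- 1L
    y <- as.numeric(fire)
  }
  dt <- attr(f, "frame_step") %||% 1
  spike_raster(q, dt)
}

#' Spike count and sparsity of a raster
#'
#' @param r A [spike_raster()].
#' @return A tibble with `n_spikes` (total ones) and `sparsity`
#'   (fraction of zero entries).
#' @export
spike_metrics <- function(r) {
  stopifnot(inherits(r, "spike_raster"))
  if (length(r) == 0) stop_input("empty raster")
  n <- sum(r)
  tibble::tibble(n_spikes = as.integer(n),
                 sparsity = 1 - n / length(r))
}

#' Full waveform-to-spikes encoder
#'
#' Composition of [extract_features()], optional [align_to_length()],
#' [normalize_features()] and [sigma_delta_encode()]. Deterministic for a
#' fixed configuration.
#'
#' @param w A [waveform()].
#' @param config An [encoder_config()].
#' @return A 39-channel [spike_raster()].
#' @export
encode_utterance <- function(w, config = encoder_config()) {
  f <- extract_features(w, config$frame_length, config$frame_step,
                        config$n_mel, config$context_n, config$pre_emphasis)
  if (!is.null(config$target_frames)) {
    f <- align_to_length(f, config$target_frames)
  }
  f <- normalize_features(f, config$epsilon)
  sigma_delta_encode(f, config)
}
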