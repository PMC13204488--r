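test_that("feature extraction yields the 39-row block layout", {
  f <- extract_features(toy_waveform())
  expect_equal(nrow(f), 39)
  expect_gt(ncol(f), 30)
  expect_true(all(is.finite(f)))
  expect_error(extract_features(waveform(rnorm(50), 12500)), "shorter")
})

test_that("dynamic features follow the central-difference estimator", {
  # inject a cepstral ramp c_t = a * t directly into the derivative stage
  a <- 0.7
  tt <- 20
  static <- matrix(rep(a * seq_len(tt), each = 13), 13, tt)
  d1 <- fbnlsm:::delta_features(static, 2)
  # interior frames: delta = (1*2a + 2*4a) / (2*(1+4)) = a
  expect_equal(d1[1, 3:(tt - 2)], rep(a, tt - 4), tolerance = 1e-12)
  d2 <- fbnlsm:::delta_features(d1, 2)
  expect_equal(d2[1, 5:(tt - 4)], rep(0, tt - 8), tolerance = 1e-12)
  # constant coefficients -> zero dynamics everywhere (replicate padding)
  flat <- matrix(5, 13, 10)
  expect_true(all(fbnlsm:::delta_features(flat, 2) == 0))
})

test_that("DTW matches brute-force path enumeration", {
  set.seed(33)
  # fixed toy cases
  expect_equal(dtw_warp(1:4, 1:4)$distance, 0)
  expect_equal(dtw_warp(1, 2)$distance, 1)
  p <- dtw_warp(matrix(rnorm(12), 3), matrix(rnorm(12), 3))$path
  expect_equal(p[1, ], c(1, 1))
  expect_equal(p[nrow(p), ], c(4, 4))
  expect_true(all(diff(p[, 1]) %in% 0:1) && all(diff(p[, 2]) %in% 0:1))
  # 200 random pairs, lengths <= 6
  for (i in 1:200) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    a <- matrix(rnorm(2 * na), 2)
    b <- matrix(rnorm(2 * nb), 2)
    got <- dtw_warp(a, b)$distance
    expect_equal(got, dtw_bruteforce(euclid_cost(a, b)), tolerance = 1e-10)
  }
})

test_that("DTW is symmetric and zero on identical sequences", {
  set.seed(44)
  for (i in 1:20) {
    a <- matrix(rnorm(8), 2)
    b <- matrix(rnorm(10), 2)
    expect_equal(dtw_warp(a, b)$distance, dtw_warp(b, a)$distance,
                 tolerance = 1e-10)
    expect_equal(dtw_warp(a, a)$distance, 0)
  }
})

test_that("alignment applies the warp path column means", {
  fs <- 0.01
  f <- feature_matrix(matrix(rep(1:6, each = 39), 39, 6), fs)
  out <- align_to_length(f, 3)
  # verify against a direct application of the returned path
  grid <- seq(1, 6, length.out = 3)
  ref <- unclass(f)[, floor(grid)] * (1 - (grid - floor(grid))) +
    unclass(f)[, ceiling(grid)] * (grid - floor(grid))
  path <- dtw_warp(unclass(f), ref)$path
  for (j in 1:3) {
    expect_equal(out[, j],
                 rowMeans(unclass(f)[, path[path[, 2] == j, 1], drop = FALSE]),
                 ignore_attr = TRUE)
  }
  # already at target length: unchanged
  expect_equal(unclass(align_to_length(f, 6)), unclass(f), ignore_attr = TRUE)
  # self as reference: diagonal path, unchanged
  expect_equal(unclass(align_to_length(f, 6, reference = f)), unclass(f),
               ignore_attr = TRUE)
})

test_that("layer normalization standardises each frame", {
  col <- c(1, 2, 3)
  f <- feature_matrix(matrix(rep(col, 13), 39, 3, byrow = FALSE), 0.01)
  # a column of repeated [1,2,3] blocks has population SD of the block
  set.seed(55)
  f2 <- feature_matrix(matrix(rnorm(39 * 7, sd = 4), 39, 7), 0.01)
  n2 <- normalize_features(f2)
  expect_true(all(abs(colMeans(unclass(n2))) < 1e-9))
  expect_equal(apply(unclass(n2), 2, function(x) sqrt(mean((x - mean(x))^2))),
               rep(1, 7), tolerance = 1e-6)
  # direct arithmetic on the 3-value column (population SD)
  z <- (col - mean(col)) / (sqrt(mean((col - mean(col))^2)) + 1e-8)
  expect_equal(z, c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  # constant column maps to zeros
  fc <- feature_matrix(matrix(3, 39, 2), 0.01)
  expect_true(all(normalize_features(fc) == 0))
  # idempotent up to epsilon effects
  expect_equal(unclass(normalize_features(n2)), unclass(n2), tolerance = 1e-6)
})

test_that("Sigma-Delta modulation follows the hand-iterated recurrences", {
  cfg1 <- encoder_config(theta = 1, alpha = 0)
  pad <- function(x) feature_matrix(rbind(matrix(x, 1, length(x)),
                                          matrix(0, 38, length(x))), 0.01)
  # constant 0.5: period-2 limit cycle, 50 spikes in 100 steps
  r <- sigma_delta_encode(pad(rep(0.5, 100)), cfg1)
  expect_equal(sum(r[1, ]), 50)
  expect_equal(r[1, 1:4], c(0, 1, 0, 1), ignore_attr = TRUE)
  # constant 1: every step
  expect_equal(sum(sigma_delta_encode(pad(rep(1, 100)), cfg1)[1, ]), 100)
  # zero input: silent
  expect_equal(sum(sigma_delta_encode(pad(rep(0, 100)), cfg1)), 0)
  # long-run rate tracks x / theta
  for (x in c(0.2, 0.7)) {
    n <- 4000
    r <- sigma_delta_encode(pad(rep(x, n)), cfg1)
    expect_lt(abs(sum(r[1, ]) / n - x), 1 / n + 1e-9)
  }
})

test_that("Sigma-Delta deficit is bounded for alpha = 0", {
  set.seed(66)
  for (i in 1:50) {
    x <- runif(200)
    f <- feature_matrix(rbind(matrix(x, 1), matrix(0, 38, 200)), 0.01)
    y <- as.numeric(sigma_delta_encode(f, encoder_config(theta = 1))[1, ])
    deficits <- abs(cumsum(x - y))
    expect_lte(max(deficits), 1 + max(abs(x)) + 1e-9)
  }
})

test_that("raster metrics count spikes and sparsity", {
  z <- spike_raster(matrix(0L, 39, 100), 0.01)
  m <- spike_metrics(z)
  expect_equal(m$n_spikes, 0L)
  expect_equal(m$sparsity, 1)
  r <- matrix(0L, 39, 100)
  r[cbind(1:39, 1:39)] <- 1L
  m2 <- spike_metrics(spike_raster(r, 0.01))
  expect_equal(m2$n_spikes, 39L)
  expect_equal(m2$sparsity, 0.99)
})

test_that("the one-call encoder equals its stage-by-stage composition", {
  w <- toy_waveform()
  cfg <- encoder_config(target_frames = 30)
  once <- encode_utterance(w, cfg)
  manual <- sigma_delta_encode(
    normalize_features(
      align_to_length(
        extract_features(w, cfg$frame_length, cfg$frame_step, cfg$n_mel,
                         cfg$context_n, cfg$pre_emphasis),
        cfg$target_frames),
      cfg$epsilon),
    cfg)
  expect_identical(unclass(once), unclass(manual))
  expect_equal(nrow(once), 39)
  # determinism
  expect_identical(unclass(encode_utterance(w, cfg)), unclass(once))
})
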