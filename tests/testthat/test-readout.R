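test_that("templates are distinct, periodic, equal-length and deterministic", {
  tpl <- make_templates(paste0("c", 1:10), duration = 600, base_rate = 10,
                        phase_step = 5, t_start = 10)
  expect_length(tpl, 10)
  expect_true(all(lengths(tpl) == 6))  # 10 Hz over 600 ms
  key <- vapply(tpl, paste, character(1), collapse = ",")
  expect_equal(anyDuplicated(key), 0)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_gt(van_rossum_distance(tpl[[i]], tpl[[j]]), 0)
  }
  expect_identical(tpl, make_templates(paste0("c", 1:10), 600, 10, 5, 10))
  expect_error(make_templates(c("a", "b"), 600, base_rate = 10,
                              phase_step = 0), "identical")
})

test_that("van Rossum distance has metric-like basics", {
  expect_equal(van_rossum_distance(c(10, 50), c(10, 50)), 0)
  expect_equal(van_rossum_distance(numeric(0), numeric(0)), 0)
  a <- c(5, 40, 90); b <- c(7, 60)
  expect_equal(van_rossum_distance(a, b), van_rossum_distance(b, a))
  expect_gt(van_rossum_distance(a, numeric(0)), 0)
  # a single spike against silence has distance sqrt(1/2)
  expect_equal(van_rossum_distance(10, numeric(0)), sqrt(0.5))
})

test_that("the ReSuMe delta matches direct evaluation and is antisymmetric", {
  # one desired spike at t, no actual, one input spike 5 ms earlier
  d <- resume_step(0, s_in = 95, s_a = numeric(0), s_d = 100)
  expect_equal(d, 0.25 + 0.1 * exp(-5 / 20), tolerance = 1e-12)
  # identical trains: zero
  expect_equal(resume_step(0, s_in = c(10, 20), s_a = c(30, 60),
                           s_d = c(30, 60)), 0)
  # spurious actual spike: negative
  expect_lt(resume_step(0, s_in = 25, s_a = 30, s_d = numeric(0)), 0)
  # antisymmetry in (s_a, s_d)
  set.seed(12)
  for (i in 1:20) {
    s_in <- sort(runif(5, 0, 100))
    s_a <- sort(runif(3, 0, 100))
    s_d <- sort(runif(4, 0, 100))
    expect_equal(resume_step(0, s_in, s_a, s_d),
                 -resume_step(0, s_in, s_d, s_a), tolerance = 1e-12)
  }
})

test_that("a single readout neuron learns a desired train from rich input", {
  set.seed(7)
  trains <- lapply(1:90, function(j) sort(sample(450, 8)))
  desired <- seq(50, 440, by = 50)
  fit <- resume_fit(trains, desired, duration = 450, cycles = 240)
  h <- fit$history
  expect_lt(tail(h$vr_distance, 1), h$vr_distance[1])
  expect_lte(tail(h$vr_distance, 1), 0.5 * h$vr_distance[1])
  expect_true(all(is.finite(fit$weights)))
})

test_that("readout training is deterministic, bounded, and improving", {
  aud <- gen_audio_dataset(n_classes = 2, n_train = 2, n_test = 1, seed = 11)
  cfg <- encoder_config(target_frames = 40)
  enc <- lapply(aud$waveform, encode_utterance, config = cfg)
  tr <- aud$split == "train"
  train <- labeled_spike_set(enc[tr], aud$class[tr])
  res <- initialize_reservoir(generate_ws_topology(90, 8, 0.1, seed = 3),
                              seed = 5)
  m1 <- train_readout(train, res, cycles = 80, seed = 7)
  m2 <- train_readout(train, res, cycles = 80, seed = 7)
  expect_identical(m1$weights, m2$weights)
  expect_true(all(abs(m1$weights) <= m1$params$w_max))
  expect_true(all(is.finite(m1$weights)))
  # own-class distance at the end is no worse than at cycle 1
  expect_lte(tail(m1$history$mean_vr_distance, 1),
             m1$history$mean_vr_distance[1] + 1e-9)
})

test_that("classification picks the own-template-closest class and breaks ties low", {
  # synthetic model with hand-set weights is overkill; check the tie rule and
  # the template-identity case through the distance computation directly
  classes <- c("a", "b")
  tpl <- make_templates(classes, 400, base_rate = 10, t_start = 50)
  # an output matching template a exactly is classified a
  d_a <- van_rossum_distance(tpl[["a"]], tpl[["a"]])
  d_b <- van_rossum_distance(numeric(0), tpl[["b"]])
  expect_lt(d_a, d_b)
  expect_equal(classes[which.min(c(d_a, d_b))], "a")
  # exact tie: lowest class index
  expect_equal(classes[which.min(c(0.5, 0.5))], "a")
})

test_that("two well-separated classes reach high test accuracy end-to-end", {
  aud <- gen_audio_dataset(n_classes = 2, n_train = 8, n_test = 5, seed = 21)
  cfg <- encoder_config(target_frames = 40)
  enc <- lapply(aud$waveform, encode_utterance, config = cfg)
  tr <- aud$split == "train"
  train <- labeled_spike_set(enc[tr], aud$class[tr])
  test <- labeled_spike_set(enc[!tr], aud$class[!tr])
  res <- initialize_reservoir(generate_ws_topology(90, 8, 0.1, seed = 3),
                              seed = 5)
  m <- train_readout(train, res, cycles = 240, seed = 7)
  ev <- evaluate_readout(m, test)
  expect_gte(attr(ev, "accuracy"), 0.8)
})

test_that("tidy and glance summarise fitted readouts", {
  aud <- gen_audio_dataset(n_classes = 2, n_train = 1, n_test = 1, seed = 11)
  enc <- lapply(aud$waveform, encode_utterance,
                config = encoder_config(target_frames = 30))
  tr <- aud$split == "train"
  train <- labeled_spike_set(enc[tr], aud$class[tr])
  res <- initialize_reservoir(generate_ws_topology(45, 4, 0.1, seed = 1),
                              seed = 2)
  m <- train_readout(train, res, cycles = 5, seed = 3)
  td <- tidy(m)
  expect_equal(nrow(td), 45 * 2)
  expect_named(td, c("reservoir_neuron", "class", "weight"))
  gl <- glance(m)
  expect_equal(gl$n_classes, 2)
  expect_equal(gl$cycles, 5)
})
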