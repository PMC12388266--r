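test_that("configuration validation lists every violation by name", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  err <- tryCatch(synthetic_config(f0 = -1, unvoiced_gain = 0.2,
                                   hf_noise_sigma = -0.5),
                  error = function(e) conditionMessage(e))
  expect_match(err, "f0 must be positive")
  expect_match(err, "unvoiced_gain")
  expect_match(err, "hf_noise_sigma")
  expect_error(synthetic_config(rate = 1000, f0 = 120, n_harmonics = 8),
               "aliasing")
  expect_error(synthetic_config(segments = data.frame(
    start = c(0, 0.1), end = c(0.3, 0.4), kind = "voiced", gain = 1,
    stringsAsFactors = FALSE), duration = 1), "overlap")
})

test_that("clean generation follows the voiced/unvoiced envelope contract", {
  expect_length(generate_clean(synthetic_config(duration = 0))$samples, 0)

  voiced <- synthetic_config(duration = 0.4, segments = data.frame(
    start = 0, end = 0.4, kind = "voiced", gain = 1))
  unvoiced <- synthetic_config(duration = 0.4, segments = data.frame(
    start = 0, end = 0.4, kind = "unvoiced", gain = 1))
  expect_lt(max(abs(generate_clean(unvoiced)$samples)),
            0.05 * max(abs(generate_clean(voiced)$samples)))

  cfg <- synthetic_config(seed = 5)
  expect_identical(generate_clean(cfg), generate_clean(cfg))
  cfg2 <- synthetic_config(seed = 6)
  expect_false(identical(generate_clean(cfg), generate_clean(cfg2)))
})

test_that("a voiced signal concentrates its energy at the harmonics", {
  cfg <- synthetic_config(duration = 0.5, onset_ms = 5, segments = data.frame(
    start = 0, end = 0.5, kind = "voiced", gain = 1), jitter = FALSE)
  x <- generate_clean(cfg)$samples
  P <- Mod(stats::fft(x))^2
  n <- length(x)
  bins <- integer(0)
  for (k in 1:cfg$n_harmonics) {
    centre <- round(k * cfg$f0 * n / cfg$rate) + 1
    bins <- c(bins, (centre - 2):(centre + 2))
  }
  bins <- unique(c(bins, n + 2 - bins))    # mirrored negative frequencies
  expect_gt(sum(P[bins]) / sum(P), 0.80)
})

test_that("added noise has the configured variance and degrades similarity", {
  cfg <- synthetic_config(hf_noise_sigma = 0, lf_amp = 0)
  clean <- generate_clean(cfg)
  expect_identical(add_noise(clean, cfg), clean)

  # white-noise variance (drift disabled to isolate it)
  cfg2 <- synthetic_config(duration = 12.5, hf_noise_sigma = 0.3, lf_amp = 0)
  clean2 <- generate_clean(cfg2)     # 1e5 samples
  noisy2 <- add_noise(clean2, cfg2, seed = 7)
  v <- stats::var(noisy2$samples - clean2$samples)
  expect_lt(abs(v - 0.09) / 0.09, 0.05)

  # similarity decreases monotonically with the noise level
  rhos <- vapply(c(0.05, 0.15, 0.4, 0.8), function(s) {
    cfgs <- synthetic_config(hf_noise_sigma = s, seed = 9)
    cl <- generate_clean(cfgs)
    ppmcc(cl, add_noise(cl, cfgs, seed = 10))
  }, numeric(1))
  expect_true(all(diff(rhos) < 0))
})

test_that("composite score of the noisy signal falls as noise grows", {
  scores <- vapply(c(0.05, 0.2, 0.5), function(s) {
    cfgs <- synthetic_config(hf_noise_sigma = s, seed = 12)
    rec <- synthesize_recording(cfgs)
    evaluate_denoising(rec$clean, rec$noisy)$composite_score
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("channel fusion is linear superposition", {
  a <- time_series(rnorm(50), 100)
  z <- time_series(rep(0, 50), 100)
  expect_equal(superpose_channels(a, z), a)
  b <- time_series(rnorm(50), 100)
  expect_equal(superpose_channels(a, b), superpose_channels(b, a))
  expect_error(superpose_channels(a, time_series(rnorm(40), 100)),
               "equal length")
  expect_error(superpose_channels(a, time_series(rnorm(50), 200)), "rate")

  # gains (1, 0.6) over a common noiseless source scale it by 1.6
  cfg <- synthetic_config(hf_noise_sigma = 0, lf_amp = 0,
                          channel_gains = c(1, 0.6))
  base <- generate_clean(cfg)
  rec <- synthesize_recording(cfg)
  expect_equal(rec$noisy$samples, 1.6 * base$samples, tolerance = 1e-12)
  expect_equal(rec$clean$samples, rec$noisy$samples, tolerance = 1e-12)
})

test_that("the charge-force relation is linear and sign-preserving", {
  expect_identical(pvdf_charge(1e-4, d = 2e-12), 2e-16)
  expect_identical(pvdf_charge(0, d = 2e-12), 0)
  f <- c(-0.3, 0.1, 2)
  expect_identical(pvdf_charge(-f, d = 3e-12), -pvdf_charge(f, d = 3e-12))
  expect_error(pvdf_charge(1, d = 0), "positive")
})

test_that("the training-set factory emits aligned normalized pairs", {
  cfg <- quick_synth()
  set1 <- make_training_set(cfg, n_examples = 40, L = 32)
  expect_identical(dim(set1$noisy), c(32L, 40L))
  expect_identical(dim(set1$clean), c(32L, 40L))
  expect_lt(max(abs(colMeans(set1$noisy))), 1e-10)

  set2 <- make_training_set(cfg, n_examples = 40, L = 32)
  expect_identical(set1, set2)

  clean_cfg <- synthetic_config(duration = 0.5, hf_noise_sigma = 0,
                                lf_amp = 0, seed = 11)
  set3 <- make_training_set(clean_cfg, n_examples = 20, L = 16)
  expect_equal(set3$noisy, set3$clean, tolerance = 1e-12)
})
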