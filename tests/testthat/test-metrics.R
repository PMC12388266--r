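test_that("spectral flatness is the geometric/arithmetic PSD ratio", {
  expect_equal(flatness_from_psd(rep(3.7, 50)), 1)
  expect_equal(flatness_from_psd(c(1, 4)), 0.8)
  set.seed(41)
  for (rep in 1:20) {
    P <- rexp(sample(2:100, 1))
    f <- flatness_from_psd(P)
    expect_gte(f, 0); expect_lte(f, 1)
  }
  expect_error(flatness_from_psd(c(1, -1)), "nonnegative")

  expect_identical(spectral_flatness(rep(0, 100)), 0)
  # a pure tone is far less flat than white noise
  set.seed(42)
  tone <- sin(2 * pi * 40 * (0:999) / 1000)
  noise <- rnorm(1000)
  expect_lt(spectral_flatness(tone), 0.01)
  expect_gt(spectral_flatness(noise), 0.5)
  # DC offsets are excluded from the PSD
  expect_equal(spectral_flatness(noise + 100), spectral_flatness(noise))
  expect_error(spectral_flatness(1), "at least 2")
})

test_that("ppmcc behaves as a Pearson correlation", {
  x <- c(0.3, 1.2, -0.5, 2.2, 0.9)
  expect_equal(ppmcc(x, 2 * x + 3), 1)
  expect_equal(ppmcc(x, -x), -1)
  expect_equal(ppmcc(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(ppmcc(x, rep(1, 5)), "constant")
  expect_error(ppmcc(x, x[1:3]), "equal length")
})

test_that("local noise energy is the mean per-frame population variance", {
  expect_equal(local_noise_energy(rep(2, 300), 100), 0)
  expect_equal(local_noise_energy(c(1, -1, 1, -1), 2), 1)
  set.seed(43)
  x <- rnorm(500)
  expect_equal(local_noise_energy(3 * x, 50), 9 * local_noise_energy(x, 50))
  # brute-force double-sum oracle over all small frame lengths
  for (L in 2:10)
    expect_lt(abs(local_noise_energy(x, L) - brute_lne(x, L)), 1e-12)
  expect_error(local_noise_energy(rnorm(10), 100), "shorter than one frame")
  expect_error(local_noise_energy(x, 1), "at least 2")
})

test_that("energy ratio compares signal energies", {
  x <- rnorm(100)
  expect_equal(energy_ratio(x, x), 1)
  expect_equal(energy_ratio(x, rep(0, 100)), 0)
  expect_equal(energy_ratio(x, x / 2), 0.25)
  expect_error(energy_ratio(rep(0, 10), rnorm(10)), "zero energy")
})

test_that("composite score saturates at 0.1 and is monotone", {
  expect_equal(composite_score(1, 0, 0), 100)
  expect_equal(round(composite_score(0.9953, 0.001301, 0.020290), 2), 93.33)
  expect_equal(round(composite_score(0.9872, 0.001395, 0.119986), 2), 69.07)

  # monotone: worse flatness or noise never raises the score
  set.seed(44)
  for (rep in 1:20) {
    rho <- runif(1, -1, 1); fl <- runif(1, 0, 0.2); ln <- runif(1, 0, 0.2)
    s <- composite_score(rho, fl, ln)
    expect_lte(composite_score(rho, fl + 0.01, ln), s + 1e-12)
    expect_lte(composite_score(rho, fl, ln + 0.01), s + 1e-12)
    expect_gte(composite_score(rho + 0.01, fl, ln), s - 1e-12)
  }
  # anything at or beyond saturation contributes nothing
  expect_equal(composite_score(0.5, 0.1, 5), composite_score(0.5, 2, 0.1))
})

test_that("evaluate populates a self-consistent report", {
  set.seed(45)
  x <- time_series(sin(2 * pi * 6 * (0:799) / 800) + 0.05 * rnorm(800), 800)
  r <- evaluate_denoising(x, x)
  expect_equal(r$ppmcc, 1)
  expect_equal(r$energy_ratio, 1)
  expect_equal(r$composite_score,
               composite_score(r$ppmcc, r$spectral_flatness,
                               r$local_noise_energy, r$weights),
               tolerance = 1e-9)

  # added white noise strictly increases the local noise energy
  den <- x
  lne0 <- evaluate_denoising(x, den)$local_noise_energy
  for (seed in 1:5) {
    set.seed(seed)
    noisier <- time_series(den$samples + rnorm(800, sd = 0.2), 800)
    expect_gt(evaluate_denoising(x, noisier)$local_noise_energy, lne0)
  }
})

test_that("reports serialize to tables and key=value text", {
  set.seed(46)
  x <- time_series(rnorm(400), 100)
  y <- time_series(x$samples + rnorm(400, sd = 0.1), 100)
  rep1 <- evaluate_denoising(x, y)
  rep2 <- evaluate_denoising(x, x)
  tab <- comparison_table(list(CNN = rep1, `Adam-DBNs` = rep2))
  expect_identical(names(tab), c("Parameter", "CNN", "Adam-DBNs"))
  expect_identical(tab$Parameter,
                   c("Spectral Flatness", "PPMCC", "Local Noise Energy",
                     "Composite Score"))
  expect_identical(nrow(tab), 4L)

  p <- tempfile()
  write_report(rep1, p)
  lines <- readLines(p)
  kv <- strsplit(lines, "=")
  expect_identical(vapply(kv, `[[`, "", 1)[1:5],
                   c("spectral_flatness", "ppmcc", "local_noise_energy",
                     "energy_ratio", "composite_score"))
  expect_equal(as.numeric(kv[[2]][2]), rep1$ppmcc, tolerance = 1e-15)
})
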