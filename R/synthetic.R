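#' Synthetic throat-vibration signals
#'
#' Seeded stand-in for live throat recordings: a harmonic pulse-train
#' surrogate of vocal-fold vibration (a fundamental plus `1/k`-decaying
#' harmonics) gated by a voiced/unvoiced segment envelope with smooth
#' raised-cosine onsets, contaminated by white high-frequency noise and a
#' slow sinusoidal baseline drift, and optionally observed through two
#' channels of different gain that are fused by linear superposition.
#'
#' @name synthetic
NULL

default_segments <- function(duration) {
  if (duration <= 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      kind = character(0), gain = numeric(0)))
  seg <- data.frame(
    start = c(0.000, 0.225, 0.400, 0.650, 0.775),
    end   = c(0.225, 0.400, 0.650, 0.775, 1.000),
    kind  = c("voiced", "unvoiced", "voiced", "unvoiced", "voiced"),
    gain  = c(1.0, 1.0, 1.3, 1.0, 1.0))
  seg$start <- seg$start * duration
  seg$end <- seg$end * duration
  seg
}

#' Synthetic-signal configuration
#'
#' Defaults describe a 2 s utterance-like trace at 8 kHz: fundamental 120 Hz
#' with 8 harmonics, alternating voiced/unvoiced segments (the middle voiced
#' segment louder, mimicking a stressed phase), 20 ms onsets, white noise
#' with a standard deviation equal to the voiced RMS, a 2 Hz baseline drift
#' at 0.2 of the voiced RMS, and channel gains (1.0, 0.6).
#'
#' @param rate sampling rate (samples/s); must exceed twice the highest
#'   harmonic frequency.
#' @param duration signal duration in seconds (0 gives an empty series).
#' @param f0 fundamental frequency in Hz.
#' @param n_harmonics number of harmonics, amplitudes decaying as `1/k`.
#' @param amplitude peak amplitude of the fundamental (voiced gain 1).
#' @param segments data.frame with columns `start`, `end` (seconds), `kind`
#'   (`"voiced"`/`"unvoiced"`) and `gain`; non-overlapping, within duration.
#' @param onset_ms envelope rise/fall time in milliseconds.
#' @param unvoiced_gain residual amplitude factor of unvoiced segments
#'   (must stay below 0.05).
#' @param hf_noise_sigma standard deviation of the additive white noise.
#' @param lf_amp,lf_freq amplitude and frequency of the baseline drift.
#' @param channel_gains gains `(g1, g2)` of the two sensor channels.
#' @param jitter randomize harmonic phases (seeded)?
#' @param seed integer seed.
#' @return a validated `synthetic_config`.
#' @export
synthetic_config <- function(rate = 8000, duration = 2, f0 = 120,
                             n_harmonics = 8, amplitude = 0.16,
                             segments = default_segments(duration),
                             onset_ms = 20, unvoiced_gain = 0.02,
                             hf_noise_sigma = 0.14, lf_amp = 0.028,
                             lf_freq = 2, channel_gains = c(1.0, 0.6),
                             jitter = TRUE, seed = 1L) {
  cfg <- list(rate = rate, duration = duration, f0 = f0,
              n_harmonics = as.integer(n_harmonics), amplitude = amplitude,
              segments = segments, onset_ms = onset_ms,
              unvoiced_gain = unvoiced_gain,
              hf_noise_sigma = hf_noise_sigma, lf_amp = lf_amp,
              lf_freq = lf_freq, channel_gains = channel_gains,
              jitter = isTRUE(jitter), seed = as.integer(seed))
  problems <- character(0)
  if (rate <= 0) problems <- c(problems, "rate must be positive")
  if (duration < 0) problems <- c(problems, "duration must be nonnegative")
  if (f0 <= 0) problems <- c(problems, "f0 must be positive")
  if (n_harmonics < 1) problems <- c(problems, "n_harmonics must be >= 1")
  if (rate <= 2 * f0 * n_harmonics)
    problems <- c(problems, sprintf(
      "rate (%g) must exceed twice the highest harmonic (2 * %g * %d = %g) to avoid aliasing",
      rate, f0, n_harmonics, 2 * f0 * n_harmonics))
  if (amplitude <= 0) problems <- c(problems, "amplitude must be positive")
  if (unvoiced_gain < 0 || unvoiced_gain >= 0.05)
    problems <- c(problems, "unvoiced_gain must lie in [0, 0.05)")
  if (hf_noise_sigma < 0) problems <- c(problems, "hf_noise_sigma must be >= 0")
  if (lf_amp < 0) problems <- c(problems, "lf_amp must be >= 0")
  if (any(channel_gains < 0) || length(channel_gains) != 2L)
    problems <- c(problems, "channel_gains must be two nonnegative numbers")
  if (nrow(segments)) {
    if (!all(c("start", "end", "kind", "gain") %in% names(segments)))
      problems <- c(problems, "segments needs columns start, end, kind, gain")
    else {
      seg <- segments[order(segments$start), ]
      if (any(seg$end <= seg$start))
        problems <- c(problems, "each segment must end after it starts")
      if (any(seg$start < 0) || any(seg$end > duration + 1e-9))
        problems <- c(problems, "segments must lie within [0, duration]")
      if (nrow(seg) > 1L && any(seg$start[-1L] < seg$end[-nrow(seg)] - 1e-9))
        problems <- c(problems, "segments must not overlap")
      if (!all(seg$kind %in% c("voiced", "unvoiced")))
        problems <- c(problems, "segment kind must be voiced or unvoiced")
      if (any(seg$gain < 0)) problems <- c(problems, "segment gains must be >= 0")
    }
  }
  if (length(problems))
    stop("invalid synthetic configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

# Smooth gating envelope: raised-cosine rise/fall of onset_ms at the segment
# borders (shortened for very short segments).
segment_envelope <- function(t, cfg) {
  env <- numeric(length(t))
  r <- cfg$onset_ms / 1000
  for (i in seq_len(nrow(cfg$segments))) {
    seg <- cfg$segments[i, ]
    g <- seg$gain * if (seg$kind == "unvoiced") cfg$unvoiced_gain else 1
    ramp <- min(r, (seg$end - seg$start) / 2)
    inside <- t >= seg$start & t < seg$end
    ti <- t[inside]
    e <- rep(1, length(ti))
    if (ramp > 0) {
      rise <- ti < seg$start + ramp
      fall <- ti >= seg$end - ramp
      e[rise] <- 0.5 - 0.5 * cos(pi * (ti[rise] - seg$start) / ramp)
      e[fall] <- 0.5 - 0.5 * cos(pi * (seg$end - ti[fall]) / ramp)
    }
    env[inside] <- env[inside] + g * e
  }
  env
}

#' Generate a clean vocal-fold-like vibration signal
#'
#' Sum of `n_harmonics` sinusoids at multiples of `f0` with `1/k` amplitude
#' decay (seeded random phases when `jitter` is on), gated by the segment
#' envelope. Unvoiced segments carry only the small `unvoiced_gain` residual.
#'
#' @param cfg a [synthetic_config()].
#' @return a [time_series] of `round(duration * rate)` samples.
#' @export
generate_clean <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- round(cfg$duration * cfg$rate)
  if (n == 0L) return(time_series(numeric(0), cfg$rate))
  t <- (seq_len(n) - 1L) / cfg$rate
  set.seed(cfg$seed)
  phases <- if (cfg$jitter) stats::runif(cfg$n_harmonics, 0, 2 * pi)
            else numeric(cfg$n_harmonics)
  wave <- numeric(n)
  for (k in seq_len(cfg$n_harmonics))
    wave <- wave + (cfg$amplitude / k) *
      sin(2 * pi * k * cfg$f0 * t + phases[k])
  time_series(wave * segment_envelope(t, cfg), cfg$rate)
}

#' Add high-frequency noise and baseline drift to a clean signal
#'
#' `clean + hf_noise_sigma * white noise
#'        + lf_amp * sin(2 pi lf_freq t + phase)` with a seeded random drift
#' phase. With both noise amplitudes zero the output equals the input
#' exactly.
#'
#' @param clean a [time_series].
#' @param cfg a [synthetic_config()].
#' @param seed integer seed for the noise draw (defaults to `cfg$seed`).
#' @return a noisy [time_series] of the same length.
#' @export
add_noise <- function(clean, cfg = synthetic_config(), seed = cfg$seed) {
  stopifnot(inherits(clean, "time_series"), inherits(cfg, "synthetic_config"))
  n <- length(clean$samples)
  if (n == 0L) return(clean)
  if (cfg$hf_noise_sigma == 0 && cfg$lf_amp == 0) return(clean)
  set.seed(seed)
  t <- (seq_len(n) - 1L) / clean$rate
  phase <- stats::runif(1L, 0, 2 * pi)
  noisy <- clean$samples +
    cfg$hf_noise_sigma * stats::rnorm(n) +
    cfg$lf_amp * sin(2 * pi * cfg$lf_freq * t + phase)
  time_series(noisy, clean$rate)
}

#' Fuse two sensor channels by linear superposition
#'
#' @param ch1,ch2 [time_series] of equal length and rate.
#' @return their element-wise sum.
#' @export
superpose_channels <- function(ch1, ch2) {
  stopifnot(inherits(ch1, "time_series"), inherits(ch2, "time_series"))
  if (length(ch1$samples) != length(ch2$samples))
    stop("channels must have equal length", call. = FALSE)
  if (ch1$rate != ch2$rate)
    stop("channels must share a sampling rate", call. = FALSE)
  time_series(ch1$samples + ch2$samples, ch1$rate)
}

#' Piezoelectric charge-force relation
#'
#' `Q = d * F`: the charge generated by a piezoelectric film is proportional
#' to the applied force, with the sign of the charge following the sign of
#' the force (reversing the force direction reverses the surface potential).
#'
#' @param force applied force in newtons (vectorized).
#' @param d piezoelectric coefficient in C/N, positive.
#' @return charge in coulombs.
#' @export
pvdf_charge <- function(force, d) {
  if (!is.numeric(d) || length(d) != 1L || d <= 0)
    stop("piezoelectric coefficient `d` must be a single positive number",
         call. = FALSE)
  d * force
}

#' Scale and contaminate the two sensor channels of a configuration
#'
#' Internal helper shared by the training-set factory and the benchmark:
#' each channel observes the clean source through its gain with its own
#' independent noise draw; the fused observation is their superposition.
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed.
#' @return list with `clean` (gain-summed clean source) and `noisy` (fused
#'   two-channel observation), both [time_series].
#' @export
synthesize_recording <- function(cfg = synthetic_config(), seed = cfg$seed) {
  clean <- generate_clean(cfg)
  g <- cfg$channel_gains
  ch1 <- add_noise(time_series(g[1L] * clean$samples, clean$rate), cfg,
                   seed = seed)
  ch2 <- add_noise(time_series(g[2L] * clean$samples, clean$rate), cfg,
                   seed = seed + 1L)
  list(clean = time_series((g[1L] + g[2L]) * clean$samples, clean$rate),
       noisy = superpose_channels(ch1, ch2))
}

#' Paired training windows for supervised denoising
#'
#' Draws `n_examples` aligned (noisy, clean) windows from one synthesized
#' recording via the trajectory embedding: random window positions (seeded),
#' each noisy window normalized to zero mean and unit population sd, and the
#' clean target expressed in the same normalized coordinates (the
#' coordinates the reconstruction network works in, whose inverse is applied
#' at prediction time).
#'
#' @param cfg a [synthetic_config()].
#' @param n_examples number of window pairs.
#' @param L window length.
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return list with `noisy` and `clean` (`L x n_examples` matrices),
#'   `positions`, and the underlying `clean_signal`/`noisy_signal`.
#' @export
make_training_set <- function(cfg = synthetic_config(), n_examples = 512L,
                              L = 64L, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"), n_examples >= 1)
  rec <- synthesize_recording(cfg, seed = seed)
  T_len <- length(rec$noisy$samples)
  if (T_len < L)
    stop(sprintf("configured duration yields %d samples, fewer than one window (L = %d)",
                 T_len, L), call. = FALSE)
  set.seed(seed + 2L)
  pos <- sample.int(T_len - L + 1L, n_examples, replace = n_examples > T_len - L + 1L)
  idx <- outer(seq_len(L) - 1L, pos, `+`) + 1L
  noisy_w <- matrix(rec$noisy$samples[idx], nrow = L)
  clean_w <- matrix(rec$clean$samples[idx], nrow = L)
  mu <- colMeans(noisy_w)
  centred <- sweep(noisy_w, 2L, mu)
  sdv <- pmax(sqrt(colMeans(centred^2)), SIGMA_FLOOR)
  list(noisy = sweep(centred, 2L, sdv, `/`),
       clean = sweep(sweep(clean_w, 2L, mu), 2L, sdv, `/`),
       positions = pos,
       clean_signal = rec$clean, noisy_signal = rec$noisy)
}
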