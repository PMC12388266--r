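#' Short-time Fourier analysis with Hanning windowing
#'
#' Frames start at sample `n = 0` with no centring or padding: frame `m`
#' covers samples `mH + 1 .. mH + N` (1-based) and is multiplied by the
#' analysis window before an `N`-point DFT. The inverse transform performs
#' per-frame inverse DFTs, windowed overlap-add, and division by the
#' accumulated squared window, which reconstructs the analyzed span exactly
#' (away from the edges) for overlap-satisfying choices such as a Hanning
#' window with 75% overlap.
#'
#' @name timefreq
NULL

#' Hanning (raised-cosine) window
#'
#' `w[n] = 1/2 - 1/2 cos(2 pi n / (N - 1))` for `n = 0 .. N-1`: zero at both
#' endpoints, symmetric, peak 1 at the centre for odd `N`. Tapering the frame
#' this way suppresses the spectral leakage a rectangular cut would cause.
#'
#' @param N window length in samples, at least 2.
#' @return numeric vector of length `N`.
#' @examples
#' hanning_window(5)
#' @export
hanning_window <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || N != as.integer(N) || N < 2)
    stop(sprintf("invalid window length N = %s (need an integer >= 2)",
                 format(N)), call. = FALSE)
  n <- seq_len(N) - 1
  0.5 - 0.5 * cos(2 * pi * n / (N - 1))
}

new_spectrogram <- function(coeffs, fft_size, hop, window, rate = NULL,
                            n_samples = NULL) {
  structure(
    list(coeffs = coeffs, fft_size = fft_size, hop = hop, window = window,
         frame_count = nrow(coeffs), rate = rate, n_samples = n_samples),
    class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d frames x %d bins (N = %d, hop = %d)\n",
              x$frame_count, x$fft_size, x$fft_size, x$hop))
  invisible(x)
}

#' Short-time Fourier transform
#'
#' @param x a [time_series] or numeric vector, at least `N` samples long.
#' @param N FFT size (frame length).
#' @param H hop between consecutive frames, `1 <= H <= N`.
#' @param window analysis window of length `N`; Hanning by default.
#' @return a `spectrogram` whose `coeffs` is a complex `frames x N` matrix,
#'   `coeffs[m, k] = sum_n x[n + (m-1)H] w[n] exp(-i 2 pi (k-1) n / N)`.
#' @export
stft <- function(x, N = 256L, H = 64L, window = hanning_window(N)) {
  s <- as_samples(x)
  N <- as.integer(N); H <- as.integer(H)
  if (length(s) < N)
    stop(sprintf("signal of length %d is shorter than one frame (N = %d)",
                 length(s), N), call. = FALSE)
  if (H < 1L || H > N)
    stop(sprintf("hop H = %d must satisfy 1 <= H <= N = %d", H, N),
         call. = FALSE)
  if (length(window) != N)
    stop("`window` must have length N", call. = FALSE)
  M <- (length(s) - N) %/% H + 1L
  starts <- (seq_len(M) - 1L) * H
  frames <- matrix(s[outer(seq_len(N), starts, `+`)], nrow = N) * window
  coeffs <- t(stats::mvfft(frames))
  new_spectrogram(coeffs, N, H, window, rate = rate_of(x),
                  n_samples = length(s))
}

#' Spectral-mask configuration
#'
#' Controls the optional magnitude masking stage. `method = "none"` is a
#' bit-identical passthrough (the default pipeline behaviour);
#' `"soft_threshold"` subtracts a per-bin noise floor from the magnitudes,
#' where the floor is the `floor_quantile` quantile of that bin's magnitude
#' across frames, with the gain clamped below by `gain_floor` and above by 1.
#' Phase is always preserved.
#'
#' @param method `"none"` or `"soft_threshold"`.
#' @param floor_quantile quantile in `[0, 1)` used as the per-bin noise floor.
#' @param gain_floor minimum retained gain in `[0, 1]`.
#' @export
mask_config <- function(method = c("none", "soft_threshold"),
                        floor_quantile = 0.10, gain_floor = 0.05) {
  method <- match.arg(method)
  if (!is.numeric(floor_quantile) || floor_quantile < 0 || floor_quantile >= 1)
    stop("`floor_quantile` must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(gain_floor) || gain_floor < 0 || gain_floor > 1)
    stop("`gain_floor` must lie in [0, 1]", call. = FALSE)
  structure(list(method = method, floor_quantile = floor_quantile,
                 gain_floor = gain_floor), class = "mask_config")
}

#' Apply a magnitude mask to a spectrogram
#'
#' @param S a `spectrogram`.
#' @param cfg a [mask_config()].
#' @return a `spectrogram` with per-bin gains in `[gain_floor, 1]` applied to
#'   the magnitudes; magnitudes never increase.
#' @export
apply_mask <- function(S, cfg = mask_config()) {
  stopifnot(inherits(S, "spectrogram"), inherits(cfg, "mask_config"))
  if (cfg$method == "none") return(S)
  mag <- Mod(S$coeffs)
  tau <- apply(mag, 2L, stats::quantile, probs = cfg$floor_quantile,
               names = FALSE)
  gain <- sweep(mag, 2L, tau) / mag       # (|X| - tau) / |X|
  gain[!is.finite(gain)] <- cfg$gain_floor  # |X| = 0 bins
  gain <- pmin(pmax(gain, cfg$gain_floor), 1)
  out <- S
  out$coeffs <- S$coeffs * gain
  out
}

#' Inverse short-time Fourier transform
#'
#' Windowed overlap-add synthesis: each frame is inverse-DFT'd, multiplied by
#' the analysis window again, accumulated at its hop position, and the result
#' is divided by the accumulated squared window. Positions where the
#' normalizer is interior yet vanishes indicate a hop/window combination that
#' cannot be inverted and raise an error.
#'
#' @param S a `spectrogram`.
#' @return a [time_series] (or numeric vector when no rate is known) covering
#'   the analyzed span of length `N + (M - 1) H`.
#' @export
istft <- function(S) {
  stopifnot(inherits(S, "spectrogram"))
  N <- S$fft_size; H <- S$hop; M <- S$frame_count; w <- S$window
  out_len <- N + (M - 1L) * H
  num <- numeric(out_len)
  den <- numeric(out_len)
  frames <- Re(stats::mvfft(t(S$coeffs), inverse = TRUE)) / N  # N x M
  for (m in seq_len(M)) {
    pos <- (m - 1L) * H + seq_len(N)
    num[pos] <- num[pos] + frames[, m] * w
    den[pos] <- den[pos] + w^2
  }
  interior <- if (out_len >= 2L * N) seq.int(N, out_len - N + 1L) else integer(0)
  if (length(interior) && any(den[interior] < 1e-12))
    stop("degenerate overlap: squared-window normalizer vanishes on the interior; choose a smaller hop",
         call. = FALSE)
  den[den < 1e-12] <- 1  # edge samples with no usable normalization pass raw
  out <- num / den
  if (is.null(S$rate)) out else time_series(out, S$rate)
}

#' STFT-domain preprocessing of a signal
#'
#' Runs analysis, optional magnitude masking, and resynthesis. Trailing
#' samples not covered by a full frame are passed through unmodified, so the
#' output always has the length of the input. With `method = "none"` (the
#' default) the signal passes through the STFT round-trip, which is an
#' identity away from the edges.
#'
#' @param x a [time_series] or numeric vector.
#' @param N,H FFT size and hop.
#' @param mask a [mask_config()].
#' @return an object of the same kind as `x`.
#' @export
stft_preprocess <- function(x, N = 256L, H = 64L, mask = mask_config()) {
  s <- as_samples(x)
  if (length(s) < N) return(x)  # too short to frame: passthrough
  S <- stft(s, N = N, H = H)
  y <- istft(apply_mask(S, mask))
  y <- as_samples(y)
  out <- s
  out[seq_along(y)] <- y
  if (is.null(rate_of(x))) out else time_series(out, rate_of(x))
}
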