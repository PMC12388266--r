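#' Denoising evaluation metrics
#'
#' The suite combines a frequency-domain residual-noise measure (spectral
#' flatness), a time-domain similarity measure (Pearson correlation), a
#' fine-grained residual-jitter measure (local noise energy), the energy
#' ratio, and a weighted composite score on a 0-100 scale.
#'
#' @name metrics
NULL

#' Spectral flatness of a power spectral density
#'
#' Ratio of the geometric to the arithmetic mean of the PSD: 1 for a flat
#' (white) spectrum, approaching 0 for a line spectrum. By the AM-GM
#' inequality the value always lies in `[0, 1]`.
#'
#' @param P nonnegative PSD values. Zeros are floored at `1e-20` before the
#'   logarithm.
#' @return flatness in `[0, 1]`.
#' @export
flatness_from_psd <- function(P) {
  if (any(P < 0)) stop("PSD values must be nonnegative", call. = FALSE)
  if (length(P) < 1L || all(P == 0)) return(0)
  Pf <- pmax(P, 1e-20)
  exp(mean(log(Pf))) / mean(Pf)
}

#' Spectral flatness of a signal
#'
#' The PSD estimator is the magnitude-squared DFT periodogram of the whole
#' signal with the DC bin excluded (so a constant offset does not register as
#' a spectral line). Lower values indicate less broadband noise residual. An
#' all-zero signal is defined to have flatness 0.
#'
#' @param x a [time_series] or numeric vector, length at least 2.
#' @return flatness in `[0, 1]`.
#' @export
spectral_flatness <- function(x) {
  s <- as_samples(x)
  if (length(s) < 2L)
    stop("spectral flatness needs at least 2 samples", call. = FALSE)
  if (all(s == 0)) return(0)
  P <- Mod(stats::fft(s))^2
  flatness_from_psd(P[-1L])
}

#' Pearson product-moment correlation of two signals
#'
#' Waveform-similarity measure in `[-1, 1]`; affine-invariant, so amplitude
#' scaling and offsets do not affect it.
#'
#' @param x,y signals of equal length (at least 2), neither constant.
#' @return correlation coefficient.
#' @export
ppmcc <- function(x, y) {
  sx <- as_samples(x, "x"); sy <- as_samples(y, "y")
  if (length(sx) != length(sy))
    stop("signals must have equal length", call. = FALSE)
  if (length(sx) < 2L)
    stop("correlation needs at least 2 samples", call. = FALSE)
  if (stats::var(sx) == 0 || stats::var(sy) == 0)
    stop("correlation is undefined for a constant signal", call. = FALSE)
  stats::cor(sx, sy)
}

#' Local noise energy
#'
#' Mean over non-overlapping frames of the per-frame population variance
#' (divide by the frame length); a localized intra-frame variance average
#' that captures residual high-frequency jitter. A trailing partial frame is
#' discarded.
#'
#' @param x a [time_series] or numeric vector covering at least one frame.
#' @param frame_length frame length in samples (default 100, at least 2).
#' @return nonnegative scalar.
#' @export
local_noise_energy <- function(x, frame_length = 100L) {
  s <- as_samples(x)
  frame_length <- as.integer(frame_length)
  if (frame_length < 2L) stop("`frame_length` must be at least 2", call. = FALSE)
  M <- length(s) %/% frame_length
  if (M < 1L)
    stop(sprintf("signal of length %d is shorter than one frame (%d samples)",
                 length(s), frame_length), call. = FALSE)
  frames <- matrix(s[seq_len(M * frame_length)], nrow = frame_length)
  centred <- sweep(frames, 2L, colMeans(frames))
  mean(colMeans(centred^2))
}

#' Energy ratio of denoised to original signal
#'
#' @param original,denoised signals of equal length; `original` must carry
#'   nonzero energy.
#' @return `sum(denoised^2) / sum(original^2)`.
#' @export
energy_ratio <- function(original, denoised) {
  so <- as_samples(original, "original"); sd_ <- as_samples(denoised, "denoised")
  if (length(so) != length(sd_))
    stop("signals must have equal length", call. = FALSE)
  eo <- sum(so^2)
  if (eo == 0) stop("original signal has zero energy", call. = FALSE)
  sum(sd_^2) / eo
}

#' Weighted composite denoising score
#'
#' `100 * (W1 * rho + W2 * (1 - min(1, flatness / 0.1))
#'        + W3 * (1 - min(1, lne / 0.1)))`:
#' similarity is rewarded directly while flatness and local noise energy are
#' mapped through a 0.1 saturation so that anything at or above 0.1
#' contributes nothing. Defaults weights: `(0.4, 0.3, 0.3)`.
#'
#' @param ppmcc similarity coefficient `rho`.
#' @param flatness spectral flatness of the denoised signal.
#' @param lne local noise energy of the denoised signal.
#' @param weights nonnegative weights `(W1, W2, W3)`.
#' @return score; 100 for a perfect, noise-free reconstruction.
#' @export
composite_score <- function(ppmcc, flatness, lne, weights = c(0.4, 0.3, 0.3)) {
  stopifnot(length(weights) == 3L, all(weights >= 0))
  100 * (weights[1L] * ppmcc +
         weights[2L] * (1 - pmin(1, flatness / 0.1)) +
         weights[3L] * (1 - pmin(1, lne / 0.1)))
}

#' Evaluate a denoised signal against its original
#'
#' Populates the full metric report: flatness and local noise energy are
#' computed on the denoised signal, the correlation between original and
#' denoised, and the composite score from the three.
#'
#' @param original,denoised signals of equal length.
#' @param frame_length frame length for [local_noise_energy()].
#' @param weights composite-score weights.
#' @return a `metric_report`: list with fields `spectral_flatness`, `ppmcc`,
#'   `local_noise_energy`, `energy_ratio`, `composite_score`, `weights`.
#' @export
evaluate_denoising <- function(original, denoised, frame_length = 100L,
                               weights = c(0.4, 0.3, 0.3)) {
  rho <- ppmcc(original, denoised)
  fl <- spectral_flatness(denoised)
  lne <- local_noise_energy(denoised, frame_length)
  er <- energy_ratio(original, denoised)
  structure(
    list(spectral_flatness = fl, ppmcc = rho, local_noise_energy = lne,
         energy_ratio = er,
         composite_score = composite_score(rho, fl, lne, weights),
         weights = weights, frame_length = as.integer(frame_length)),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Denoising metric report\n")
  cat(sprintf("  Spectral Flatness   %.6f\n", x$spectral_flatness))
  cat(sprintf("  PPMCC               %.4f\n", x$ppmcc))
  cat(sprintf("  Local Noise Energy  %.6f\n", x$local_noise_energy))
  cat(sprintf("  Energy Ratio        %.4f\n", x$energy_ratio))
  cat(sprintf("  Composite Score     %.2f\n", x$composite_score))
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(spectral_flatness = x$spectral_flatness, ppmcc = x$ppmcc,
             local_noise_energy = x$local_noise_energy,
             energy_ratio = x$energy_ratio,
             composite_score = x$composite_score)
}

#' Side-by-side comparison table for several metric reports
#'
#' Rows are the metrics, one column per method, mirroring the usual
#' benchmark-table layout (scores printed to 2 decimals, raw values stored
#' unrounded in the reports).
#'
#' @param reports named list of `metric_report` objects.
#' @return a data.frame with a `Parameter` column and one column per method.
#' @export
comparison_table <- function(reports) {
  stopifnot(length(reports) >= 1L, !is.null(names(reports)))
  cols <- lapply(reports, function(r)
    c(sprintf("%.6f", r$spectral_flatness),
      sprintf("%.4f", r$ppmcc),
      sprintf("%.6f", r$local_noise_energy),
      sprintf("%.2f", r$composite_score)))
  out <- data.frame(Parameter = c("Spectral Flatness", "PPMCC",
                                  "Local Noise Energy", "Composite Score"),
                    cols, check.names = FALSE)
  names(out) <- c("Parameter", names(reports))
  out
}

#' Serialize a metric report as flat key=value text
#'
#' @param x a `metric_report`.
#' @param path optional file; when `NULL` the lines are returned.
#' @return the lines, invisibly when written to a file.
#' @export
write_report <- function(x, path = NULL) {
  stopifnot(inherits(x, "metric_report"))
  lines <- c(
    sprintf("spectral_flatness=%.17g", x$spectral_flatness),
    sprintf("ppmcc=%.17g", x$ppmcc),
    sprintf("local_noise_energy=%.17g", x$local_noise_energy),
    sprintf("energy_ratio=%.17g", x$energy_ratio),
    sprintf("composite_score=%.17g", x$composite_score),
    sprintf("weights=%.17g,%.17g,%.17g", x$weights[1L], x$weights[2L],
            x$weights[3L]))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
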