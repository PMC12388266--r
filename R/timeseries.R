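#' Uniformly sampled vibration signal
#'
#' Container for a 1-D real time series, the universal currency of the
#' pipeline: a vector of sensor voltages (arbitrary units) plus its sampling
#' rate. All samples must be finite.
#'
#' @param samples numeric vector of samples. May be empty.
#' @param rate sampling rate in samples per second; a single positive number.
#' @return an object of class `"time_series"` with fields `samples` and `rate`.
#' @examples
#' x <- time_series(sin(2 * pi * 5 * seq(0, 1, by = 1 / 100)), rate = 100)
#' x
#' @export
time_series <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number", call. = FALSE)
  if (length(samples) && !all(is.finite(samples)))
    stop("`samples` must be finite (no NA/NaN/Inf)", call. = FALSE)
  structure(list(samples = samples, rate = as.numeric(rate)),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("<time_series> %d samples @ %g Hz (%.4g s)\n",
              n, x$rate, n / x$rate))
  if (n) {
    head_n <- utils::head(x$samples, 6L)
    cat("  ", paste(signif(head_n, 5), collapse = ", "),
        if (n > 6L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$samples)

# Accept either a time_series or a bare numeric vector; return the samples.
as_samples <- function(x, arg = "x") {
  if (inherits(x, "time_series")) return(x$samples)
  if (is.numeric(x)) return(as.numeric(x))
  stop(sprintf("`%s` must be a time_series or a numeric vector", arg),
       call. = FALSE)
}

# Rate of a time_series, or NULL for a bare vector.
rate_of <- function(x) if (inherits(x, "time_series")) x$rate else NULL
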