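#' Hankel trajectory-matrix embedding and diagonal averaging
#'
#' A signal `x[1..T]` is embedded into an `L x K` Hankel matrix
#' (`K = T - L + 1`) whose column `j` is the window `x[j .. j+L-1]`, so every
#' anti-diagonal is constant. Diagonal averaging is the exact inverse: entry
#' `t` of the reconstruction is the mean of all matrix elements with
#' `i + j = t + 1` (1-based). The embedding strengthens the local temporal
#' structure seen by the reconstruction network; diagonal averaging maps
#' per-window network outputs back to one signal, averaging up to `L`
#' independent estimates of each sample.
#'
#' @name trajectory
NULL

new_trajectory_matrix <- function(values, rate = NULL, means = NULL,
                                  stds = NULL, normalized = FALSE) {
  structure(
    list(values = values,
         window_length = nrow(values),
         n_columns = ncol(values),
         column_means = means,
         column_stds = stds,
         normalized = normalized,
         rate = rate),
    class = "trajectory_matrix")
}

#' @export
print.trajectory_matrix <- function(x, ...) {
  cat(sprintf("<trajectory_matrix> L = %d, K = %d%s%s\n",
              x$window_length, x$n_columns,
              if (x$normalized) ", normalized" else "",
              if (!is.null(x$rate)) sprintf(", rate %g Hz", x$rate) else ""))
  invisible(x)
}

#' Build the sliding-window trajectory matrix of a signal
#'
#' @param x a [time_series] or numeric vector of length `T`.
#' @param L window length, `1 <= L <= T`.
#' @return a `trajectory_matrix` whose `values` field is the `L x (T - L + 1)`
#'   Hankel matrix; not yet normalized.
#' @examples
#' build_trajectory_matrix(c(1, 2, 3, 4), L = 2)$values
#' @seealso [diagonal_average()] for the exact inverse.
#' @export
build_trajectory_matrix <- function(x, L) {
  s <- as_samples(x)
  T_len <- length(s)
  if (!is.numeric(L) || length(L) != 1L || L != as.integer(L))
    stop("`L` must be a single integer", call. = FALSE)
  L <- as.integer(L)
  if (L < 1L || L > T_len)
    stop(sprintf("invalid window length L = %d for signal of length %d (need 1 <= L <= T)",
                 L, T_len), call. = FALSE)
  K <- T_len - L + 1L
  # values[i, j] = x[i + j - 1]
  V <- matrix(s[outer(seq_len(L), seq_len(K) - 1L, `+`)], nrow = L, ncol = K)
  new_trajectory_matrix(V, rate = rate_of(x))
}

# Floor applied to column standard deviations so constant windows stay finite.
SIGMA_FLOOR <- 1e-8

#' Normalize a trajectory matrix by columns
#'
#' Each column is centred by its mean and scaled by its population standard
#' deviation (divide by `n`), bringing every window onto a common scale before
#' spectral analysis or network input. Constant columns (sd below `1e-8`) are
#' mapped to zeros with the sd floored, so no division by zero can occur. The
#' statistics are stored for exact inversion by [denormalize_columns()].
#'
#' @param X a `trajectory_matrix` that has not been normalized yet.
#' @return the normalized `trajectory_matrix` with `column_means` and
#'   `column_stds` populated.
#' @export
normalize_columns <- function(X) {
  stopifnot(inherits(X, "trajectory_matrix"))
  if (isTRUE(X$normalized))
    stop("trajectory matrix is already normalized", call. = FALSE)
  V <- X$values
  mu <- colMeans(V)
  centred <- sweep(V, 2L, mu)
  sdv <- sqrt(colMeans(centred^2))
  sdv <- pmax(sdv, SIGMA_FLOOR)
  Vn <- sweep(centred, 2L, sdv, `/`)
  new_trajectory_matrix(Vn, rate = X$rate, means = mu, stds = sdv,
                        normalized = TRUE)
}

#' Invert a column normalization
#'
#' Maps network output (or any matrix in normalized coordinates) back to the
#' original signal scale: column `j` becomes `x * sd_j + mean_j`.
#'
#' @param X a normalized `trajectory_matrix` with stored statistics.
#' @param values optional replacement matrix in normalized coordinates (same
#'   shape); defaults to `X$values`. Used to denormalize model reconstructions
#'   with the statistics of their inputs.
#' @return a `trajectory_matrix` on the original scale (`normalized = FALSE`).
#' @export
denormalize_columns <- function(X, values = NULL) {
  stopifnot(inherits(X, "trajectory_matrix"))
  if (!isTRUE(X$normalized) || is.null(X$column_means) || is.null(X$column_stds))
    stop("trajectory matrix is not normalized (no stored statistics to invert)",
         call. = FALSE)
  V <- if (is.null(values)) X$values else values
  if (!identical(dim(V), dim(X$values)))
    stop("replacement `values` must match the matrix dimensions", call. = FALSE)
  Vd <- sweep(sweep(V, 2L, X$column_stds, `*`), 2L, X$column_means, `+`)
  new_trajectory_matrix(Vd, rate = X$rate)
}

#' Anti-diagonal element counts of an L x K matrix
#'
#' `n_t` is the number of elements on anti-diagonal `t` (`i + j = t + 1`),
#' following the piecewise form: `t` while `t <= min(L, K)`, then constant
#' `min(L, K)`, then `L + K - t`.
#'
#' @param L,K matrix dimensions.
#' @return integer vector of length `L + K - 1`.
#' @export
antidiagonal_counts <- function(L, K) {
  stopifnot(L >= 1, K >= 1)
  t <- seq_len(L + K - 1L)
  pmin(t, min(L, K), L + K - t)
}

#' Reconstruct a signal by diagonal averaging
#'
#' Output element `t` is the mean of all entries on anti-diagonal `t`. For a
#' Hankel matrix built by [build_trajectory_matrix()] this recovers the
#' original signal exactly; for an arbitrary matrix (e.g. per-window model
#' output) it is the least-squares consistent signal estimate.
#'
#' @param X a `trajectory_matrix` or a plain numeric matrix.
#' @return a [time_series] when a sampling rate is known, otherwise a numeric
#'   vector, of length `D = L + K - 1`.
#' @export
diagonal_average <- function(X) {
  rate <- NULL
  if (inherits(X, "trajectory_matrix")) {
    rate <- X$rate
    V <- X$values
  } else if (is.matrix(X) && is.numeric(X)) {
    V <- X
  } else {
    stop("`X` must be a trajectory_matrix or a numeric matrix", call. = FALSE)
  }
  if (length(V) == 0L)
    stop("cannot diagonal-average an empty matrix", call. = FALSE)
  L <- nrow(V); K <- ncol(V)
  sums <- numeric(L + K - 1L)
  idx <- as.vector(row(V) + col(V)) - 1L
  sums <- vapply(split(as.vector(V), idx), sum, numeric(1))
  out <- as.numeric(sums) / antidiagonal_counts(L, K)
  if (is.null(rate)) out else time_series(out, rate)
}
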