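#' Restricted Boltzmann machine layers
#'
#' A two-layer undirected energy model with `D` visible and `F` hidden units
#' and no intra-layer connections. Two unit types are supported:
#'
#' * `bernoulli`: binary visibles, energy
#'   `E(v, h) = -sum a_i v_i - sum b_j h_j - sum v_i W_ij h_j`;
#' * `gauss_bernoulli`: continuous Gaussian visibles with per-unit scales
#'   `sigma_i`, energy
#'   `E(v, h) = sum (v_i - a_i)^2 / (2 sigma_i^2) - sum b_j h_j
#'              - sum (v_i / sigma_i) W_ij h_j`,
#'   suited to real-valued normalized signal windows.
#'
#' The conditionals used everywhere follow from these energies:
#' `P(h_j = 1 | v) = sigmoid(b_j + sum_i (v_i / sigma_i) W_ij)` and, for the
#' visible layer, a Gaussian with mean `a_i + sigma_i sum_j W_ij h_j`
#' (Gauss-Bernoulli) or `sigmoid(a_i + sum_j W_ij h_j)` (Bernoulli).
#'
#' @name rbm
NULL

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Create an RBM layer
#'
#' @param n_visible,n_hidden layer dimensions `D` and `F`.
#' @param unit_type `"gauss_bernoulli"` (continuous visibles) or
#'   `"bernoulli"` (binary visibles).
#' @param init_sd standard deviation of the seeded Gaussian weight
#'   initialization; biases start at zero, scales at one.
#' @param seed optional integer; when given, initialization is reproducible.
#' @return an object of class `"rbm_layer"` with fields `W` (`D x F`), `a`
#'   (`D`), `b` (`F`), `sigma` (`D`, all 1 for Bernoulli), `unit_type`.
#' @export
rbm_layer <- function(n_visible, n_hidden,
                      unit_type = c("gauss_bernoulli", "bernoulli"),
                      init_sd = 0.01, seed = NULL) {
  unit_type <- match.arg(unit_type)
  stopifnot(n_visible >= 1, n_hidden >= 1)
  if (!is.null(seed)) set.seed(seed)
  structure(
    list(W = matrix(stats::rnorm(n_visible * n_hidden, sd = init_sd),
                    n_visible, n_hidden),
         a = numeric(n_visible),
         b = numeric(n_hidden),
         sigma = rep(1, n_visible),
         unit_type = unit_type),
    class = "rbm_layer")
}

#' @export
print.rbm_layer <- function(x, ...) {
  cat(sprintf("<rbm_layer> %s, %d visible x %d hidden\n",
              x$unit_type, nrow(x$W), ncol(x$W)))
  invisible(x)
}

check_layer_dims <- function(layer, v = NULL, h = NULL) {
  D <- nrow(layer$W); F_ <- ncol(layer$W)
  if (!is.null(v) && NROW(v) != D)
    stop(sprintf("visible vector has length %d but layer expects D = %d",
                 NROW(v), D), call. = FALSE)
  if (!is.null(h) && NROW(h) != F_)
    stop(sprintf("hidden vector has length %d but layer expects F = %d",
                 NROW(h), F_), call. = FALSE)
  invisible(TRUE)
}

#' Energy of a visible/hidden configuration
#'
#' @param v visible vector of length `D`.
#' @param h hidden (0/1) vector of length `F`.
#' @param layer an [rbm_layer()].
#' @return scalar energy.
#' @export
rbm_energy <- function(v, h, layer) {
  stopifnot(inherits(layer, "rbm_layer"))
  check_layer_dims(layer, v = v, h = h)
  v <- as.numeric(v); h <- as.numeric(h)
  if (layer$unit_type == "bernoulli") {
    -sum(layer$a * v) - sum(layer$b * h) - drop(crossprod(v, layer$W %*% h))
  } else {
    sum((v - layer$a)^2 / (2 * layer$sigma^2)) - sum(layer$b * h) -
      drop(crossprod(v / layer$sigma, layer$W %*% h))
  }
}

#' Hidden-unit activation probabilities
#'
#' `P(h_j = 1 | v) = sigmoid(b_j + sum_i (v_i / sigma_i) W_ij)`; for
#' Bernoulli layers `sigma_i = 1`.
#'
#' @param v visible vector (length `D`) or matrix (`D x batch`).
#' @param layer an [rbm_layer()].
#' @return vector of length `F`, or an `F x batch` matrix.
#' @export
hidden_probability <- function(v, layer) {
  stopifnot(inherits(layer, "rbm_layer"))
  V <- if (is.matrix(v)) v else matrix(v, ncol = 1L)
  check_layer_dims(layer, v = V)
  P <- sigmoid(crossprod(layer$W, V / layer$sigma) + layer$b)
  if (is.matrix(v)) P else drop(P)
}

#' Expected visible activation given hidden states
#'
#' Gauss-Bernoulli: `a_i + sigma_i sum_j W_ij h_j` (the conditional Gaussian
#' mean); Bernoulli: `sigmoid(a_i + sum_j W_ij h_j)`.
#'
#' @param h hidden vector (length `F`) or matrix (`F x batch`).
#' @param layer an [rbm_layer()].
#' @return vector of length `D`, or a `D x batch` matrix.
#' @export
visible_mean <- function(h, layer) {
  stopifnot(inherits(layer, "rbm_layer"))
  Hm <- if (is.matrix(h)) h else matrix(h, ncol = 1L)
  check_layer_dims(layer, h = Hm)
  M <- if (layer$unit_type == "gauss_bernoulli") {
    layer$W %*% Hm * layer$sigma + layer$a
  } else {
    sigmoid(layer$W %*% Hm + layer$a)
  }
  if (is.matrix(h)) M else drop(M)
}

#' One contrastive-divergence parameter update
#'
#' CD-k with seeded Bernoulli sampling of the hidden states. Visible
#' reconstructions are sampled for Bernoulli layers (keeping the expected
#' update unbiased at the model distribution) and use the conditional mean
#' for Gauss-Bernoulli layers (the usual practice for continuous units).
#' Positive statistics come from the data, negative statistics from the
#' k-step reconstruction; parameters move by `rate` times the batch-averaged
#' difference. `rate = 0` leaves the layer bit-identical.
#'
#' @param layer an [rbm_layer()].
#' @param batch visible batch, `D x n` matrix (columns are examples).
#' @param rate learning rate.
#' @param k number of Gibbs steps (`>= 1`).
#' @param seed optional integer seed making the update deterministic.
#' @return the updated [rbm_layer()].
#' @export
cd_update <- function(layer, batch, rate, k = 1L, seed = NULL) {
  stopifnot(inherits(layer, "rbm_layer"))
  if (!is.matrix(batch)) batch <- matrix(batch, ncol = 1L)
  if (ncol(batch) == 0L) stop("empty batch", call. = FALSE)
  check_layer_dims(layer, v = batch)
  if (rate == 0) return(layer)
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(batch)
  sig <- layer$sigma
  v0 <- batch
  p0 <- hidden_probability(v0, layer)
  h <- matrix(stats::runif(length(p0)) < p0, nrow = nrow(p0)) * 1
  vk <- v0; pk <- p0
  for (step in seq_len(k)) {
    vk <- visible_mean(h, layer)
    if (!is.matrix(vk)) vk <- matrix(vk, ncol = n)
    if (layer$unit_type == "bernoulli")
      vk <- matrix(stats::runif(length(vk)) < vk, nrow = nrow(vk)) * 1
    pk <- hidden_probability(vk, layer)
    if (step < k) {
      h <- matrix(stats::runif(length(pk)) < pk, nrow = nrow(pk)) * 1
    }
  }
  pos_W <- (v0 / sig) %*% t(p0)
  neg_W <- (vk / sig) %*% t(pk)
  layer$W <- layer$W + rate * (pos_W - neg_W) / n
  da <- if (layer$unit_type == "gauss_bernoulli") {
    rowMeans(v0 - vk) / sig^2
  } else {
    rowMeans(v0 - vk)
  }
  layer$a <- layer$a + rate * da
  layer$b <- layer$b + rate * rowMeans(p0 - pk)
  layer
}

#' Exact mean log-likelihood of a tiny Bernoulli RBM
#'
#' Test oracle: enumerates all `2^D` visible and `2^F` hidden states of the
#' Boltzmann distribution. Only feasible for `D + F <= 16`.
#'
#' @param layer a Bernoulli [rbm_layer()].
#' @param data visible batch, `D x n` matrix of 0/1 values.
#' @return mean log-likelihood of the columns of `data`.
#' @export
exact_bernoulli_loglik <- function(layer, data) {
  stopifnot(inherits(layer, "rbm_layer"))
  if (layer$unit_type != "bernoulli")
    stop("exact enumeration is implemented for Bernoulli layers only",
         call. = FALSE)
  D <- nrow(layer$W); F_ <- ncol(layer$W)
  if (D + F_ > 16L)
    stop(sprintf("model too large to enumerate (D + F = %d > 16)", D + F_),
         call. = FALSE)
  if (!is.matrix(data)) data <- matrix(data, ncol = 1L)
  check_layer_dims(layer, v = data)
  vs <- all_binary_states(D)
  # free energy of each visible state: -a'v - sum_j log(1 + exp(b_j + v'W_j))
  free_energy <- function(V) {
    -drop(crossprod(V, layer$a)) -
      colSums(log1p(exp(crossprod(layer$W, V) + layer$b)))
  }
  fe_all <- free_energy(vs)
  logZ <- log_sum_exp(-fe_all)
  mean(-free_energy(data) - logZ)
}

# All binary column vectors of dimension d, as a d x 2^d matrix.
all_binary_states <- function(d) {
  m <- as.matrix(expand.grid(rep(list(c(0, 1)), d)))
  t(unname(m))
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
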