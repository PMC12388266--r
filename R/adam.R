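#' Adam optimizer, from first principles
#'
#' The five-line recursion with bias-corrected first and second moments:
#' \deqn{m_t = \beta_1 m_{t-1} + (1-\beta_1) g_t}
#' \deqn{v_t = \beta_2 v_{t-1} + (1-\beta_2) g_t^2}
#' \deqn{\hat m_t = m_t / (1-\beta_1^t), \quad \hat v_t = v_t / (1-\beta_2^t)}
#' \deqn{\theta_t = \theta_{t-1} - \alpha \hat m_t / (\sqrt{\hat v_t} + \epsilon)}
#'
#' With `beta1 = beta2 = 0` the step reduces exactly to sign-normalized
#' gradient descent, `-alpha * g / (|g| + eps)`; under a constant gradient the
#' per-step displacement converges to `-alpha * sign(g)`.
#'
#' @name adam
NULL

#' Initialize Adam optimizer state
#'
#' @param n number of parameters.
#' @param alpha learning rate.
#' @param beta1,beta2 momentum coefficients in `[0, 1)`.
#' @param eps numerical stabilizer added to the root second moment.
#' @return an `adam_state` with zeroed moments and step count `t = 0`.
#' @export
adam_init <- function(n, alpha = 5e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  stopifnot(n >= 1, alpha > 0, beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1,
            eps > 0)
  structure(list(m = numeric(n), v = numeric(n), t = 0L, alpha = alpha,
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "adam_state")
}

#' One Adam update
#'
#' @param params numeric parameter vector.
#' @param grad gradient of the loss at `params`, same length.
#' @param state an [adam_init()] state (its `alpha` may be changed between
#'   calls to follow a learning-rate schedule).
#' @return `list(params, state)` with the step applied and `t` incremented.
#' @export
adam_step <- function(params, grad, state) {
  stopifnot(inherits(state, "adam_state"))
  if (length(params) != length(grad))
    stop(sprintf("params (%d) and grad (%d) differ in length",
                 length(params), length(grad)), call. = FALSE)
  if (length(params) != length(state$m))
    stop("adam state was initialized for a different parameter count",
         call. = FALSE)
  t_new <- state$t + 1L
  m <- state$beta1 * state$m + (1 - state$beta1) * grad
  v <- state$beta2 * state$v + (1 - state$beta2) * grad^2
  m_hat <- m / (1 - state$beta1^t_new)
  v_hat <- v / (1 - state$beta2^t_new)
  params <- params - state$alpha * m_hat / (sqrt(v_hat) + state$eps)
  state$m <- m; state$v <- v; state$t <- t_new
  list(params = params, state = state)
}

#' Joint time/frequency reconstruction loss
#'
#' `lambda1 * MSE(x, xhat) + lambda2 * L1(|DFT(x)|, |DFT(xhat)|)`, both terms
#' mean-reduced per element so the weights are scale-comparable. The DFT is
#' the unnormalized transform applied per window (per column for batches).
#'
#' @param lambda1 weight on the time-domain mean squared error.
#' @param lambda2 weight on the spectral-magnitude mean absolute difference.
#' @return a `loss_config`.
#' @export
loss_config <- function(lambda1 = 0.7, lambda2 = 0.3) {
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2), class = "loss_config")
}

as_window_batch <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

#' Evaluate the joint loss
#'
#' @param x target batch: numeric vector or `L x n` matrix (columns are
#'   windows).
#' @param xhat reconstruction batch, same shape.
#' @param cfg a [loss_config()].
#' @return scalar loss; zero iff `x == xhat` (when `lambda1 > 0`).
#' @export
joint_loss <- function(x, xhat, cfg = loss_config()) {
  X <- as_window_batch(x); Xh <- as_window_batch(xhat)
  if (!identical(dim(X), dim(Xh)))
    stop("target and reconstruction batches differ in shape", call. = FALSE)
  mse <- mean((X - Xh)^2)
  spec <- mean(abs(Mod(stats::mvfft(Xh)) - Mod(stats::mvfft(X))))
  cfg$lambda1 * mse + cfg$lambda2 * spec
}

# Gradient of joint_loss with respect to xhat (same shape as xhat).
# d|Z_k|/dxhat_n = Re(conj(Z_k)/|Z_k| * exp(-i 2 pi k n / N)), so the spectral
# term's gradient is Re(fft(sign_k * conj(Z_k)/|Z_k|)) / (N * B); the standard
# subgradient 0 is used where |Z_k| = 0 or the magnitudes tie.
joint_loss_grad <- function(x, xhat, cfg = loss_config()) {
  X <- as_window_batch(x); Xh <- as_window_batch(xhat)
  if (!identical(dim(X), dim(Xh)))
    stop("target and reconstruction batches differ in shape", call. = FALSE)
  n_el <- length(X)
  g <- cfg$lambda1 * 2 * (Xh - X) / n_el
  if (cfg$lambda2 > 0) {
    Z <- stats::mvfft(Xh)
    magZ <- Mod(Z)
    s <- sign(magZ - Mod(stats::mvfft(X)))
    C <- s * Conj(Z) / ifelse(magZ == 0, 1, magZ)
    C[magZ == 0] <- 0
    g <- g + cfg$lambda2 * Re(stats::mvfft(C)) / n_el
  }
  if (is.matrix(xhat)) g else drop(g)
}
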