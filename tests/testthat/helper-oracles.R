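# Independent oracles used across the suite: brute-force enumerations and
# naive reference implementations kept deliberately separate from the
# package's own computation paths.

# All binary column vectors of dimension d (enumeration order irrelevant).
enum_states <- function(d) {
  t(unname(as.matrix(expand.grid(rep(list(c(0, 1)), d)))))
}

# Boltzmann conditional P(h_j = 1 | v) by enumerating full hidden states
# through rbm_energy only.
enum_hidden_conditional <- function(layer, v) {
  F_ <- ncol(layer$W)
  hs <- enum_states(F_)
  w <- apply(hs, 2L, function(h) exp(-rbm_energy(v, h, layer)))
  as.numeric(hs %*% w) / sum(w)
}

# Boltzmann marginal p(v) over all visible states, via rbm_energy.
enum_visible_marginal <- function(layer) {
  D <- nrow(layer$W); F_ <- ncol(layer$W)
  vs <- enum_states(D); hs <- enum_states(F_)
  joint <- matrix(0, ncol(vs), ncol(hs))
  for (i in seq_len(ncol(vs)))
    for (j in seq_len(ncol(hs)))
      joint[i, j] <- exp(-rbm_energy(vs[, i], hs[, j], layer))
  p <- rowSums(joint)
  list(states = vs, p = p / sum(p))
}

# Naive double-sum local noise energy (direct transcription of the
# frame-variance average).
brute_lne <- function(x, L) {
  M <- length(x) %/% L
  total <- 0
  for (m in seq_len(M)) {
    fr <- x[((m - 1) * L + 1):(m * L)]
    total <- total + sum((fr - mean(fr))^2) / L
  }
  total / M
}

# Brute-force anti-diagonal element counts of an L x K index grid.
brute_antidiag_counts <- function(L, K) {
  counts <- integer(L + K - 1)
  for (i in seq_len(L))
    for (j in seq_len(K))
      counts[i + j - 1] <- counts[i + j - 1] + 1L
  counts
}

# Naive O(N^2) DFT of one frame (reference for the STFT kernel).
naive_dft <- function(x) {
  N <- length(x)
  vapply(0:(N - 1), function(k)
    sum(x * exp(-2i * pi * k * (0:(N - 1)) / N)), complex(1))
}

# Numerical gradient of a scalar function by central differences.
num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    a <- x; a[i] <- a[i] + eps
    b <- x; b[i] <- b[i] - eps
    (f(a) - f(b)) / (2 * eps)
  }, numeric(1))
}

# Small randomized RBM layer for oracle comparisons.
random_layer <- function(D, F_, unit_type, seed) {
  layer <- rbm_layer(D, F_, unit_type, seed = seed)
  set.seed(seed + 1L)
  layer$W <- matrix(rnorm(D * F_, sd = 0.8), D, F_)
  layer$a <- rnorm(D, sd = 0.5)
  layer$b <- rnorm(F_, sd = 0.5)
  if (unit_type == "gauss_bernoulli") layer$sigma <- runif(D, 0.5, 1.5)
  layer
}

# Tiny synthetic configuration for fast training tests.
quick_synth <- function(seed = 11L, sigma = 0.14)
  synthetic_config(duration = 0.5, hf_noise_sigma = sigma, seed = seed)
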