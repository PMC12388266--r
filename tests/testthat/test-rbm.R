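test_that("energies evaluate the closed forms", {
  lb <- rbm_layer(2, 2, "bernoulli")
  lb$W[] <- 0
  expect_identical(rbm_energy(c(1, 0), c(0, 1), lb), 0)

  lg <- random_layer(3, 2, "gauss_bernoulli", seed = 21)
  expect_equal(rbm_energy(lg$a, c(0, 0), lg), 0)

  l1 <- rbm_layer(1, 1, "bernoulli")
  l1$a <- 1; l1$b <- 2; l1$W[] <- 3
  expect_equal(rbm_energy(1, 1, l1), -6)

  expect_error(rbm_energy(c(1, 0, 0), c(0, 1), lb), "length 3.*D = 2")
})

test_that("hidden probabilities are the sigmoid conditional", {
  l0 <- rbm_layer(3, 4, "bernoulli")
  l0$W[] <- 0
  expect_equal(hidden_probability(c(1, 0, 1), l0), rep(0.5, 4))

  lsat <- rbm_layer(2, 2, "bernoulli")
  lsat$W[] <- 0; lsat$b <- c(30, 30)
  expect_equal(hidden_probability(c(0, 0), lsat), c(1, 1), tolerance = 1e-9)
})

test_that("conditionals agree with Boltzmann enumeration on all tiny models", {
  for (D in 1:4) for (F_ in 1:4) for (ut in c("bernoulli", "gauss_bernoulli")) {
    layer <- random_layer(D, F_, ut, seed = D * 100 + F_ * 10 +
                            (ut == "bernoulli"))
    v <- if (ut == "bernoulli") rbinom(D, 1, 0.5) else rnorm(D)
    expect_lt(max(abs(hidden_probability(v, layer) -
                      enum_hidden_conditional(layer, v))), 1e-10)
  }
})

test_that("visible means are the conditional expectations of the energy model", {
  lg <- random_layer(3, 2, "gauss_bernoulli", seed = 31)
  expect_equal(visible_mean(c(0, 0), lg), lg$a)

  l0 <- rbm_layer(3, 2, "bernoulli")
  l0$W[] <- 0
  expect_equal(visible_mean(c(1, 0), l0), rep(0.5, 3))

  # Gauss-Bernoulli: the conditional mean is the energy minimum in v, so the
  # energy gradient (computed numerically, independent of visible_mean)
  # vanishes there.
  for (seed in 1:3) {
    lg <- random_layer(3, 3, "gauss_bernoulli", seed = 40 + seed)
    h <- rbinom(3, 1, 0.5)
    vstar <- visible_mean(h, lg)
    g <- num_grad(function(v) rbm_energy(v, h, lg), vstar)
    expect_lt(max(abs(g)), 1e-8)
  }
})

test_that("contrastive divergence is a stochastic ascent direction", {
  layer <- random_layer(4, 2, "bernoulli", seed = 55)
  set.seed(56)
  batch <- matrix(rbinom(4 * 30, 1, 0.5), 4, 30)

  expect_identical(cd_update(layer, batch, rate = 0), layer)
  expect_error(cd_update(layer, batch[, 0, drop = FALSE], rate = 0.1),
               "empty batch")

  # expected CD-1 update direction vs the exact log-likelihood gradient
  # (finite differences of the enumerated likelihood)
  flatten <- function(l) c(l$W, l$a, l$b)
  n_rep <- 200
  deltas <- matrix(0, length(flatten(layer)), n_rep)
  for (r in seq_len(n_rep)) {
    up <- cd_update(layer, batch, rate = 1e-3, seed = 1000 + r)
    deltas[, r] <- (flatten(up) - flatten(layer)) / 1e-3
  }
  mean_dir <- rowMeans(deltas)
  theta <- flatten(layer)
  ll <- function(th) {
    l2 <- layer
    l2$W <- matrix(th[1:8], 4, 2); l2$a <- th[9:12]; l2$b <- th[13:14]
    exact_bernoulli_loglik(l2, batch)
  }
  exact_grad <- num_grad(ll, theta, eps = 1e-5)
  expect_gt(sum(mean_dir * exact_grad),
            0.5 * sqrt(sum(mean_dir^2)) * sqrt(sum(exact_grad^2)))
})

test_that("CD has zero expected update at the model distribution", {
  layer <- random_layer(2, 2, "bernoulli", seed = 77)
  marg <- enum_visible_marginal(layer)
  flatten <- function(l) c(l$W, l$a, l$b)
  n_rep <- 200
  deltas <- matrix(0, 8, n_rep)
  set.seed(78)
  for (r in seq_len(n_rep)) {
    draw <- sample.int(ncol(marg$states), 64, replace = TRUE, prob = marg$p)
    batch <- marg$states[, draw, drop = FALSE]
    up <- cd_update(layer, batch, rate = 1e-2, seed = 2000 + r)
    deltas[, r] <- (flatten(up) - flatten(layer)) / 1e-2
  }
  m <- rowMeans(deltas)
  se <- apply(deltas, 1, stats::sd) / sqrt(n_rep)
  expect_true(all(abs(m) < 3 * se))
})

test_that("exact enumeration oracle behaves like a likelihood", {
  l0 <- rbm_layer(1, 1, "bernoulli")
  l0$W[] <- 0
  expect_equal(exact_bernoulli_loglik(l0, matrix(1, 1, 1)), -log(2))

  # the enumerated distribution is normalized
  layer <- random_layer(3, 2, "bernoulli", seed = 91)
  vs <- enum_states(3)
  probs <- vapply(seq_len(ncol(vs)), function(i)
    exp(exact_bernoulli_loglik(layer, vs[, i, drop = FALSE])), numeric(1))
  expect_lt(abs(sum(probs) - 1), 1e-12)

  # small-step exact-gradient ascent increases the likelihood monotonically
  layer <- random_layer(3, 2, "bernoulli", seed = 92)
  set.seed(93)
  data <- matrix(rbinom(3 * 20, 1, c(0.8, 0.2, 0.5)), 3, 20)
  flatten <- function(l) c(l$W, l$a, l$b)
  unflatten <- function(th) {
    l2 <- layer
    l2$W <- matrix(th[1:6], 3, 2); l2$a <- th[7:9]; l2$b <- th[10:11]
    l2
  }
  th <- flatten(layer)
  lls <- numeric(51)
  lls[1] <- exact_bernoulli_loglik(layer, data)
  for (s in 1:50) {
    g <- num_grad(function(t_) exact_bernoulli_loglik(unflatten(t_), data),
                  th, eps = 1e-5)
    th <- th + 0.05 * g
    lls[s + 1] <- exact_bernoulli_loglik(unflatten(th), data)
  }
  expect_true(all(diff(lls) > 0))

  expect_error(exact_bernoulli_loglik(rbm_layer(10, 10, "bernoulli"),
                                      matrix(0, 10, 1)), "too large")
  expect_error(exact_bernoulli_loglik(rbm_layer(2, 2, "gauss_bernoulli"),
                                      matrix(0, 2, 1)), "Bernoulli")
})
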