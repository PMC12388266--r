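test_that("the model stacks a Gauss-Bernoulli layer under Bernoulli layers", {
  m <- dbn_model(input_dim = 16, hidden = c(24, 12, 8), seed = 1)
  expect_identical(m$layers[[1]]$unit_type, "gauss_bernoulli")
  expect_identical(m$layers[[2]]$unit_type, "bernoulli")
  expect_identical(m$layers[[3]]$unit_type, "bernoulli")
  # adjacent dimensions chain and the head returns to the input dimension
  expect_identical(ncol(m$layers[[1]]$W), nrow(m$layers[[2]]$W))
  expect_identical(ncol(m$layers[[2]]$W), nrow(m$layers[[3]]$W))
  expect_identical(dim(m$head_W), c(8L, 16L))
})

test_that("forward pass is deterministic, bounded, and affine in the head", {
  m <- dbn_model(input_dim = 6, hidden = c(5, 4, 3), seed = 2)
  for (l in 1:3) m$layers[[l]]$W[] <- 0
  m$head_W[] <- 0
  m$head_b <- rep(2.5, 6)
  expect_equal(dbn_forward(m, rnorm(6)), rep(2.5, 6))

  m2 <- dbn_model(input_dim = 6, hidden = c(5, 4, 3), seed = 3)
  v <- rnorm(6)
  expect_identical(dbn_forward(m2, v), dbn_forward(m2, v))
  expect_true(all(is.finite(dbn_forward(m2, rep(1e6, 6)))))
  expect_error(dbn_forward(m2, rnorm(5)), "5 rows")
})

test_that("pre-training reduces first-layer reconstruction error deterministically", {
  set.seed(30)
  data <- matrix(rnorm(16 * 80), 16, 80)
  m <- dbn_model(input_dim = 16, hidden = c(12, 8, 6), seed = 4)
  cfg <- train_config(pretrain_epochs = 8, batch_size = 16,
                      pretrain_rate = 5e-3, seed = 99)

  expect_identical(pretrain(m, data, train_config(pretrain_epochs = 0)), m)

  recon_mse <- function(model) {
    p <- hidden_probability(data, model$layers[[1]])
    mean((visible_mean(p, model$layers[[1]]) - data)^2)
  }
  trained <- pretrain(m, data, cfg)
  expect_lt(recon_mse(trained), recon_mse(m))
  expect_identical(trained, pretrain(m, data, cfg))
})

test_that("fine-tuning reduces the loss, honours the schedule, and is seeded", {
  set.seed(31)
  n <- 60
  clean <- matrix(rnorm(12 * n), 12, n)
  noisy <- clean + matrix(rnorm(12 * n, sd = 0.5), 12, n)
  m <- dbn_model(input_dim = 12, hidden = c(16, 10, 8), seed = 5)
  cfg <- train_config(pretrain_epochs = 0, finetune_epochs = 95,
                      batch_size = 16, seed = 17,
                      lr_schedule = data.frame(epoch = c(1, 90),
                                               rate = c(5e-3, 2.5e-3)))
  fit <- fine_tune(m, noisy, clean, cfg)
  h <- fit$history
  expect_identical(nrow(h), 95L)
  expect_lt(h$train_loss[95], h$train_loss[1])
  expect_identical(h$learning_rate[89], 5e-3)
  expect_identical(h$learning_rate[90], 2.5e-3)
  expect_identical(h$learning_rate[95], 2.5e-3)
  expect_false(anyNA(h$val_loss))

  fit2 <- fine_tune(m, noisy, clean, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$model, fit2$model)

  expect_error(fine_tune(m, noisy, clean[, 1:10]), "paired")
})

test_that("a near-identity model passes signals through denoise unchanged", {
  L <- 8
  eps <- 2e-3   # balances linearization error against rounding in the head
  m <- dbn_model(input_dim = L, hidden = c(L, L, L), seed = 6)
  # linearized sigmoid chain: each layer applies eps * I around 0.5, and the
  # head unwinds the accumulated (eps/4)^3 scaling
  # each layer maps x -> 0.5 + (eps/4) x + O(eps^3), so three layers give
  # 0.5 + (eps/4)^3 v; the head rescales by 64/eps^3 and removes the offset
  m$layers[[1]]$W <- diag(eps, L); m$layers[[1]]$b <- rep(0, L)
  m$layers[[2]]$W <- diag(eps, L); m$layers[[2]]$b <- rep(-eps / 2, L)
  m$layers[[3]]$W <- diag(eps, L); m$layers[[3]]$b <- rep(-eps / 2, L)
  m$head_W <- diag(64 / eps^3, L)
  m$head_b <- rep(-32 / eps^3, L)
  x <- time_series(sin(2 * pi * 3 * (0:199) / 200), 100)
  y <- denoise(m, x, L)
  expect_identical(length(y$samples), 200L)
  expect_lt(max(abs(y$samples - x$samples)), 1e-5)
})

test_that("denoised output length equals input length for random lengths", {
  m <- dbn_model(input_dim = 8, hidden = c(6, 5, 4), seed = 7)
  set.seed(33)
  for (rep in 1:50) {
    n <- sample(8:150, 1)
    y <- denoise(m, rnorm(n), 8)
    expect_identical(length(as.numeric(y)), n)
  }
})

test_that("checkpoints round-trip byte-identically and reload exactly", {
  m <- dbn_model(input_dim = 10, hidden = c(8, 6, 5), seed = 8)
  p1 <- tempfile(fileext = ".rds"); p2 <- tempfile(fileext = ".rds")
  save_model(m, p1, config = list(L = 10, note = "fixture"))
  m2 <- load_model(p1)
  save_model(m2, p2, config = attr(m2, "config"))
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  v <- rnorm(10)
  expect_identical(dbn_forward(m2, v), dbn_forward(m, v))
  expect_error(load_model(tempfile()), "not found")
  bad <- tempfile(); saveRDS(list(a = 1), bad)
  expect_error(load_model(bad), "not a piezodenoise checkpoint")
})
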