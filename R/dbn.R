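#' Deep belief network reconstructor
#'
#' Three stacked RBM layers (Gauss-Bernoulli at the bottom for continuous
#' input windows, Bernoulli above) followed by a linear regression head that
#' maps the top hidden activations back to a window of the input dimension.
#' Training proceeds in two phases: greedy layer-by-layer contrastive
#' divergence pre-training with plain SGD (no Adam), then end-to-end
#' supervised fine-tuning of all weights with Adam under the joint
#' time/frequency loss.
#'
#' @name dbn
NULL

#' Training configuration
#'
#' @param pretrain_epochs epochs of CD pre-training per layer.
#' @param finetune_epochs epochs of supervised fine-tuning (default 100).
#' @param batch_size minibatch size.
#' @param cd_steps Gibbs steps per CD update.
#' @param lr_schedule data.frame with columns `epoch` (increasing) and
#'   `rate`: the rate that takes effect from that epoch on. The default holds
#'   5e-3 until epoch 89 and halves to 2.5e-3 at epoch 90.
#' @param pretrain_rate SGD rate used during CD pre-training.
#' @param validation_fraction fraction of pairs held out for validation
#'   during fine-tuning.
#' @param seed integer seed governing every random choice (initialization,
#'   CD sampling, shuffling, the validation split).
#' @export
train_config <- function(pretrain_epochs = 15L, finetune_epochs = 100L,
                         batch_size = 32L, cd_steps = 1L,
                         lr_schedule = data.frame(epoch = c(1L, 90L),
                                                  rate = c(5e-3, 2.5e-3)),
                         pretrain_rate = 1e-3,
                         validation_fraction = 0.2, seed = 42L) {
  stopifnot(pretrain_epochs >= 0, finetune_epochs >= 1, batch_size >= 1,
            cd_steps >= 1, pretrain_rate > 0,
            validation_fraction >= 0, validation_fraction < 1)
  if (!is.data.frame(lr_schedule) ||
      !all(c("epoch", "rate") %in% names(lr_schedule)) ||
      is.unsorted(lr_schedule$epoch, strictly = TRUE))
    stop("`lr_schedule` must be a data.frame(epoch, rate) with strictly increasing epochs",
         call. = FALSE)
  structure(list(pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 batch_size = as.integer(batch_size),
                 cd_steps = as.integer(cd_steps),
                 lr_schedule = lr_schedule,
                 pretrain_rate = pretrain_rate,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

schedule_rate <- function(schedule, epoch) {
  active <- schedule$epoch <= epoch
  if (!any(active)) schedule$rate[1L] else schedule$rate[max(which(active))]
}

#' Create a DBN model
#'
#' @param input_dim window length `L` (also the output dimension).
#' @param hidden widths of the three hidden layers.
#' @param init_sd weight initialization scale (seeded Gaussian).
#' @param seed integer seed for the initialization.
#' @return an object of class `"dbn_model"`: three [rbm_layer()]s (the first
#'   Gauss-Bernoulli, the rest Bernoulli), `head_W` (top width x
#'   `input_dim`) and `head_b`.
#' @export
dbn_model <- function(input_dim = 64L, hidden = c(256L, 128L, 64L),
                      init_sd = NULL, seed = 42L) {
  stopifnot(length(hidden) == 3L, all(hidden >= 1), input_dim >= 1)
  set.seed(seed)
  dims <- c(input_dim, hidden)
  layers <- vector("list", 3L)
  for (i in 1:3) {
    sd_i <- if (is.null(init_sd)) 1 / sqrt(dims[i]) else init_sd
    layers[[i]] <- rbm_layer(dims[i], dims[i + 1L],
                             unit_type = if (i == 1L) "gauss_bernoulli"
                                         else "bernoulli",
                             init_sd = sd_i)
  }
  structure(
    list(layers = layers,
         head_W = matrix(stats::rnorm(hidden[3L] * input_dim,
                                      sd = 1 / sqrt(hidden[3L])),
                         hidden[3L], input_dim),
         head_b = numeric(input_dim),
         input_dim = as.integer(input_dim)),
    class = "dbn_model")
}

#' @export
print.dbn_model <- function(x, ...) {
  widths <- vapply(x$layers, function(l) ncol(l$W), integer(1))
  cat(sprintf("<dbn_model> %d -> %s -> %d (linear head)\n",
              x$input_dim, paste(widths, collapse = " -> "), x$input_dim))
  invisible(x)
}

#' Greedy layer-by-layer CD pre-training
#'
#' Each RBM is trained in turn with plain-SGD contrastive divergence (the
#' Adam optimizer is reserved for fine-tuning); upper layers are trained on
#' the deterministic hidden probabilities of the layer below.
#'
#' @param model a [dbn_model()].
#' @param data input windows, `input_dim x n` matrix.
#' @param cfg a [train_config()].
#' @return the pre-trained model. `pretrain_epochs = 0` returns the model
#'   unchanged.
#' @export
pretrain <- function(model, data, cfg = train_config()) {
  stopifnot(inherits(model, "dbn_model"))
  if (!is.matrix(data)) data <- matrix(data, ncol = 1L)
  if (nrow(data) != model$input_dim)
    stop(sprintf("data rows (%d) must equal the model input dimension (%d)",
                 nrow(data), model$input_dim), call. = FALSE)
  if (cfg$pretrain_epochs == 0L) return(model)
  set.seed(cfg$seed)
  layer_input <- data
  n <- ncol(data)
  for (li in seq_along(model$layers)) {
    layer <- model$layers[[li]]
    for (ep in seq_len(cfg$pretrain_epochs)) {
      perm <- sample.int(n)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
        layer <- cd_update(layer, layer_input[, idx, drop = FALSE],
                           rate = cfg$pretrain_rate, k = cfg$cd_steps)
      }
    }
    model$layers[[li]] <- layer
    layer_input <- hidden_probability(layer_input, layer)
  }
  model
}

#' Deterministic forward pass
#'
#' Three sigmoid layers (hidden probabilities, no sampling) followed by the
#' affine regression head. Bounded hidden activations keep the output finite
#' for arbitrarily large inputs.
#'
#' @param model a [dbn_model()].
#' @param v input window (length `input_dim`) or `input_dim x n` batch.
#' @return reconstruction of the same shape as `v`.
#' @export
dbn_forward <- function(model, v) {
  stopifnot(inherits(model, "dbn_model"))
  V <- if (is.matrix(v)) v else matrix(v, ncol = 1L)
  if (nrow(V) != model$input_dim)
    stop(sprintf("input has %d rows but the model expects %d",
                 nrow(V), model$input_dim), call. = FALSE)
  H <- V
  for (layer in model$layers) H <- hidden_probability(H, layer)
  out <- crossprod(model$head_W, H) + model$head_b
  if (is.matrix(v)) out else drop(out)
}

# --- parameter flattening -------------------------------------------------

dbn_params <- function(model) {
  list(W1 = model$layers[[1L]]$W, b1 = model$layers[[1L]]$b,
       W2 = model$layers[[2L]]$W, b2 = model$layers[[2L]]$b,
       W3 = model$layers[[3L]]$W, b3 = model$layers[[3L]]$b,
       head_W = model$head_W, head_b = model$head_b)
}

dbn_set_params <- function(model, params) {
  model$layers[[1L]]$W <- params$W1; model$layers[[1L]]$b <- params$b1
  model$layers[[2L]]$W <- params$W2; model$layers[[2L]]$b <- params$b2
  model$layers[[3L]]$W <- params$W3; model$layers[[3L]]$b <- params$b3
  model$head_W <- params$head_W; model$head_b <- params$head_b
  model
}

# Forward pass retaining activations for backpropagation.
dbn_forward_cache <- function(model, V) {
  sig1 <- model$layers[[1L]]$sigma
  Vs <- V / sig1
  H1 <- hidden_probability(V, model$layers[[1L]])
  H2 <- hidden_probability(H1, model$layers[[2L]])
  H3 <- hidden_probability(H2, model$layers[[3L]])
  out <- crossprod(model$head_W, H3) + model$head_b
  list(out = out, Vs = Vs, H1 = H1, H2 = H2, H3 = H3)
}

# Analytic backpropagation of dL/dout through the head and sigmoid stack.
dbn_backward <- function(model, cache, G) {
  dH3 <- model$head_W %*% G
  dZ3 <- dH3 * cache$H3 * (1 - cache$H3)
  dH2 <- model$layers[[3L]]$W %*% dZ3
  dZ2 <- dH2 * cache$H2 * (1 - cache$H2)
  dH1 <- model$layers[[2L]]$W %*% dZ2
  dZ1 <- dH1 * cache$H1 * (1 - cache$H1)
  list(W1 = cache$Vs %*% t(dZ1), b1 = rowSums(dZ1),
       W2 = cache$H1 %*% t(dZ2), b2 = rowSums(dZ2),
       W3 = cache$H2 %*% t(dZ3), b3 = rowSums(dZ3),
       head_W = cache$H3 %*% t(G), head_b = rowSums(G))
}

# Shared supervised training loop (used by the DBN fine-tuner and the CNN
# comparator): minibatch Adam on the joint loss with a learning-rate
# schedule, a seeded validation split, and a per-epoch history table.
run_supervised_training <- function(params, forward, backward,
                                    noisy, clean, cfg, loss_cfg) {
  if (!is.matrix(noisy)) noisy <- matrix(noisy, ncol = 1L)
  if (!is.matrix(clean)) clean <- matrix(clean, ncol = 1L)
  if (!identical(dim(noisy), dim(clean)))
    stop("noisy and clean batches must be paired (same dimensions)",
         call. = FALSE)
  n <- ncol(noisy)
  set.seed(cfg$seed)
  n_val <- floor(cfg$validation_fraction * n)
  val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) == 0L) stop("no training examples left after the validation split",
                                 call. = FALSE)
  skeleton <- params
  theta <- unlist(params, use.names = FALSE)
  state <- adam_init(length(theta))
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), learning_rate = numeric(0))
  for (ep in seq_len(cfg$finetune_epochs)) {
    state$alpha <- schedule_rate(cfg$lr_schedule, ep)
    perm <- tr_idx[sample.int(length(tr_idx))]
    batch_losses <- c()
    for (start in seq(1L, length(perm), by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, length(perm))]
      params <- utils::relist(theta, skeleton)
      fwd <- forward(params, noisy[, idx, drop = FALSE])
      target <- clean[, idx, drop = FALSE]
      batch_losses <- c(batch_losses, joint_loss(target, fwd$out, loss_cfg))
      G <- joint_loss_grad(target, fwd$out, loss_cfg)
      grads <- backward(params, fwd, G)
      step <- adam_step(theta, unlist(grads, use.names = FALSE), state)
      theta <- step$params
      state <- step$state
    }
    params <- utils::relist(theta, skeleton)
    val_loss <- if (length(val_idx)) {
      fwd <- forward(params, noisy[, val_idx, drop = FALSE])
      joint_loss(clean[, val_idx, drop = FALSE], fwd$out, loss_cfg)
    } else NA_real_
    history <- rbind(history,
                     data.frame(epoch = ep, train_loss = mean(batch_losses),
                                val_loss = val_loss,
                                learning_rate = state$alpha))
  }
  list(params = utils::relist(theta, skeleton), history = history)
}

#' Supervised fine-tuning of a DBN with Adam
#'
#' Full-model analytic backpropagation of the joint time/frequency loss
#' through the sigmoid stack and regression head, optimized by [adam_step()]
#' with the configured learning-rate schedule (default: 5e-3, halved at
#' epoch 90). A seeded fraction of the pairs is held out to report a
#' validation loss per epoch.
#'
#' @param model a (typically pre-trained) [dbn_model()].
#' @param noisy,clean paired window batches, `input_dim x n` matrices with
#'   matching columns.
#' @param cfg a [train_config()].
#' @param loss_cfg a [loss_config()].
#' @return `list(model, history)`; `history` is a data.frame with columns
#'   `epoch`, `train_loss`, `val_loss`, `learning_rate`.
#' @export
fine_tune <- function(model, noisy, clean, cfg = train_config(),
                      loss_cfg = loss_config()) {
  stopifnot(inherits(model, "dbn_model"))
  fit <- run_supervised_training(
    dbn_params(model),
    forward = function(params, V) dbn_forward_cache(dbn_set_params(model, params), V),
    backward = function(params, cache, G) dbn_backward(dbn_set_params(model, params), cache, G),
    noisy = noisy, clean = clean, cfg = cfg, loss_cfg = loss_cfg)
  list(model = dbn_set_params(model, fit$params), history = fit$history)
}

#' Denoise a signal with a trained model
#'
#' Runs the full reconstruction chain: trajectory embedding, column
#' normalization, deterministic forward pass per window, denormalization
#' with the stored column statistics, and diagonal averaging back to a
#' signal of the input length. Methods exist for the DBN and for the CNN
#' comparator (which processes the windows in chunks).
#'
#' @param model a trained [dbn_model()] or [cnn_init()] weight set.
#' @param x a [time_series] or numeric vector with at least `L` samples.
#' @param L trajectory window length; defaults to the model input dimension.
#' @return denoised signal of the same kind and length as `x`.
#' @export
denoise <- function(model, x, L = NULL) UseMethod("denoise")

# Shared reconstruction chain; `forward_fn` maps a normalized L x K window
# matrix to its reconstruction.
denoise_windows <- function(forward_fn, x, L) {
  X <- build_trajectory_matrix(x, L)
  Xn <- normalize_columns(X)
  out <- forward_fn(Xn$values)
  Xd <- denormalize_columns(Xn, values = out)
  y <- diagonal_average(Xd)
  if (inherits(x, "time_series") && !inherits(y, "time_series"))
    y <- time_series(y, x$rate)
  y
}

#' @rdname denoise
#' @export
denoise.dbn_model <- function(model, x, L = NULL) {
  if (is.null(L)) L <- model$input_dim
  if (L != model$input_dim)
    stop(sprintf("window length L = %d must equal the model input dimension %d",
                 L, model$input_dim), call. = FALSE)
  denoise_windows(function(V) dbn_forward(model, V), x, L)
}

#' Save or load a model checkpoint
#'
#' The checkpoint is a single self-describing archive holding every weight
#' matrix, bias vector, per-visible-unit scale, the layer dimensions and unit
#' types, the model kind, and any configuration supplied. Serialization is
#' deterministic: save -> load -> save is byte-identical.
#'
#' @param model a [dbn_model()] or a CNN weight set from [train_cnn()].
#' @param path file path for the checkpoint.
#' @param config optional configuration list stored alongside the weights.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   reconstructed model object.
#' @export
save_model <- function(model, path, config = NULL) {
  kind <- if (inherits(model, "dbn_model")) "dbn"
          else if (inherits(model, "cnn_weights")) "cnn"
          else stop("`model` must be a dbn_model or cnn_weights", call. = FALSE)
  body <- unclass(model)
  attr(body, "config") <- NULL   # carried separately so round-trips are stable
  payload <- list(format = "piezodenoise-checkpoint", version = 1L,
                  kind = kind, model = body, config = config)
  saveRDS(payload, path, version = 3L)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    stop("checkpoint file not found: ", path, call. = FALSE)
  payload <- readRDS(path)
  if (!identical(payload$format, "piezodenoise-checkpoint"))
    stop("not a piezodenoise checkpoint: ", path, call. = FALSE)
  model <- payload$model
  class(model) <- if (payload$kind == "dbn") "dbn_model" else "cnn_weights"
  attr(model, "config") <- payload$config
  model
}
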