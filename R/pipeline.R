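#' Pipeline configuration
#'
#' One flat container for every tunable of the pipeline, with validated
#' ranges and documented defaults. Values come from three layers in
#' increasing precedence: built-in defaults, a YAML configuration file, and
#' explicit overrides (e.g. command-line flags).
#'
#' @param ... named overrides of the defaults listed below.
#' @param file optional YAML file of overrides.
#'
#' @section Fields:
#' * `rate` (8000): sampling rate assumed for rate-less inputs.
#' * `L` (64): trajectory window length = network input dimension.
#' * `N`, `H` (256, 64): STFT frame size and hop (75% overlap).
#' * `mask_method` ("none"), `mask_floor_quantile` (0.10),
#'   `mask_gain_floor` (0.05): optional spectral-mask stage.
#' * `hidden` (256, 128, 64): DBN hidden-layer widths.
#' * `pretrain_epochs` (15), `pretrain_rate` (1e-3), `cd_steps` (1):
#'   CD pre-training.
#' * `finetune_epochs` (100), `batch_size` (32), `lr_initial` (5e-3),
#'   `lr_drop_epoch` (90), `lr_dropped` (2.5e-3),
#'   `validation_fraction` (0.2): supervised fine-tuning.
#' * `lambda1`, `lambda2` (0.7, 0.3): joint-loss weights.
#' * `lne_frame` (100): local-noise-energy frame length.
#' * `score_weights` (0.4, 0.3, 0.3): composite-score weights.
#' * `n_examples` (512): training pairs drawn from a synthetic recording.
#' * `seed` (42): master seed.
#' @return a validated `pipeline_config` (named list).
#' @export
pipeline_config <- function(..., file = NULL) {
  defaults <- list(
    rate = 8000, L = 64L, N = 256L, H = 64L,
    mask_method = "none", mask_floor_quantile = 0.10, mask_gain_floor = 0.05,
    hidden = c(256L, 128L, 64L),
    pretrain_epochs = 15L, pretrain_rate = 1e-3, cd_steps = 1L,
    finetune_epochs = 100L, batch_size = 32L,
    lr_initial = 5e-3, lr_drop_epoch = 90L, lr_dropped = 2.5e-3,
    validation_fraction = 0.2,
    lambda1 = 0.7, lambda2 = 0.3,
    lne_frame = 100L, score_weights = c(0.4, 0.3, 0.3),
    n_examples = 512L, seed = 42L)
  cfg <- defaults
  apply_layer <- function(cfg, layer, origin) {
    for (nm in names(layer)) {
      if (!nm %in% names(defaults))
        stop(sprintf("unknown configuration field '%s' (%s)", nm, origin),
             call. = FALSE)
      val <- layer[[nm]]
      proto <- defaults[[nm]]
      if (is.numeric(proto)) {
        val <- if (is.integer(proto)) as.integer(val) else as.numeric(val)
        if (anyNA(val))
          stop(sprintf("field '%s' must be numeric (%s)", nm, origin),
               call. = FALSE)
      }
      cfg[[nm]] <- val
    }
    cfg
  }
  if (!is.null(file)) {
    if (!file.exists(file))
      stop(sprintf("configuration file not found: %s", file), call. = FALSE)
    cfg <- apply_layer(cfg, yaml::read_yaml(file), paste0("from ", file))
  }
  cfg <- apply_layer(cfg, list(...), "override")
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  bad <- function(field, why)
    stop(sprintf("invalid configuration: field '%s' %s", field, why),
         call. = FALSE)
  if (cfg$rate <= 0) bad("rate", "must be positive")
  if (cfg$L < 1) bad("L", "must be at least 1")
  if (cfg$N < 2) bad("N", "must be at least 2")
  if (cfg$H < 1 || cfg$H > cfg$N) bad("H", "must satisfy 1 <= H <= N")
  if (!cfg$mask_method %in% c("none", "soft_threshold"))
    bad("mask_method", "must be 'none' or 'soft_threshold'")
  if (cfg$mask_floor_quantile < 0 || cfg$mask_floor_quantile >= 1)
    bad("mask_floor_quantile", "must lie in [0, 1)")
  if (cfg$mask_gain_floor < 0 || cfg$mask_gain_floor > 1)
    bad("mask_gain_floor", "must lie in [0, 1]")
  if (length(cfg$hidden) != 3L || any(cfg$hidden < 1))
    bad("hidden", "must be three positive layer widths")
  if (cfg$pretrain_epochs < 0) bad("pretrain_epochs", "must be >= 0")
  if (cfg$pretrain_rate <= 0) bad("pretrain_rate", "must be positive")
  if (cfg$cd_steps < 1) bad("cd_steps", "must be >= 1")
  if (cfg$finetune_epochs < 1) bad("finetune_epochs", "must be >= 1")
  if (cfg$batch_size < 1) bad("batch_size", "must be >= 1")
  if (cfg$lr_initial <= 0) bad("lr_initial", "must be positive")
  if (cfg$lr_dropped <= 0) bad("lr_dropped", "must be positive")
  if (cfg$lr_drop_epoch < 1) bad("lr_drop_epoch", "must be >= 1")
  if (cfg$validation_fraction < 0 || cfg$validation_fraction >= 1)
    bad("validation_fraction", "must lie in [0, 1)")
  if (cfg$lambda1 < 0) bad("lambda1", "must be >= 0")
  if (cfg$lambda2 < 0) bad("lambda2", "must be >= 0")
  if (cfg$lne_frame < 2) bad("lne_frame", "must be >= 2")
  if (length(cfg$score_weights) != 3L || any(cfg$score_weights < 0))
    bad("score_weights", "must be three nonnegative weights")
  if (cfg$n_examples < 1) bad("n_examples", "must be >= 1")
  structure(cfg, class = "pipeline_config")
}

as_train_config <- function(cfg) {
  train_config(
    pretrain_epochs = cfg$pretrain_epochs,
    finetune_epochs = cfg$finetune_epochs,
    batch_size = cfg$batch_size,
    cd_steps = cfg$cd_steps,
    lr_schedule = data.frame(epoch = c(1L, as.integer(cfg$lr_drop_epoch)),
                             rate = c(cfg$lr_initial, cfg$lr_dropped)),
    pretrain_rate = cfg$pretrain_rate,
    validation_fraction = cfg$validation_fraction,
    seed = cfg$seed)
}

as_loss_config <- function(cfg) loss_config(cfg$lambda1, cfg$lambda2)

as_mask_config <- function(cfg)
  mask_config(cfg$mask_method, cfg$mask_floor_quantile, cfg$mask_gain_floor)

#' Train the default denoising pipeline on synthetic pairs
#'
#' Convenience driver: draws paired windows from a synthesized recording,
#' pre-trains the DBN layer stack with contrastive divergence, and fine-tunes
#' with Adam under the joint loss.
#'
#' @param cfg a [pipeline_config()].
#' @param synth a [synthetic_config()]; its seed defaults to `cfg$seed`.
#' @return `list(model, history, data)`.
#' @export
train_pipeline <- function(cfg = pipeline_config(),
                           synth = synthetic_config(seed = cfg$seed)) {
  data <- make_training_set(synth, n_examples = cfg$n_examples, L = cfg$L)
  model <- dbn_model(input_dim = cfg$L, hidden = cfg$hidden, seed = cfg$seed)
  tc <- as_train_config(cfg)
  model <- pretrain(model, data$noisy, tc)
  fit <- fine_tune(model, data$noisy, data$clean, tc, as_loss_config(cfg))
  list(model = fit$model, history = fit$history, data = data)
}

#' Full signal-denoising pipeline
#'
#' Optional STFT-domain mask stage followed by the model reconstruction
#' chain (trajectory embedding, normalization, forward pass, diagonal
#' averaging). With the default `mask_method = "none"` the mask stage is a
#' bit-identical passthrough.
#'
#' @param model a trained [dbn_model()] or [cnn_init()] weight set.
#' @param x input signal.
#' @param cfg a [pipeline_config()].
#' @return denoised signal, same length as the input.
#' @export
denoise_pipeline <- function(model, x, cfg = pipeline_config()) {
  if (cfg$mask_method != "none")
    x <- stft_preprocess(x, N = cfg$N, H = cfg$H, mask = as_mask_config(cfg))
  denoise(model, x, L = cfg$L)
}

#' Train and compare the DBN and the CNN on one seeded dataset
#'
#' Both models receive the same training pairs, the same loss, the same
#' optimizer settings and the same number of training rounds; both then
#' denoise the same held-out synthetic recording and are scored against its
#' clean reference. The result mirrors the usual benchmark-table layout.
#'
#' @param cfg a [pipeline_config()]; `finetune_epochs` applies to both
#'   models.
#' @param synth a [synthetic_config()] for the data.
#' @param eval_duration duration (s) of the held-out evaluation recording.
#' @return list with `table` (comparison data.frame), `reports`, `histories`,
#'   `models`, and the evaluation `signals`.
#' @export
compare_denoisers <- function(cfg = pipeline_config(finetune_epochs = 10L,
                                                    n_examples = 192L,
                                                    pretrain_epochs = 5L),
                              synth = synthetic_config(seed = cfg$seed),
                              eval_duration = 0.5) {
  data <- make_training_set(synth, n_examples = cfg$n_examples, L = cfg$L)
  tc <- as_train_config(cfg)
  lc <- as_loss_config(cfg)

  dbn <- dbn_model(input_dim = cfg$L, hidden = cfg$hidden, seed = cfg$seed)
  dbn <- pretrain(dbn, data$noisy, tc)
  dbn_fit <- fine_tune(dbn, data$noisy, data$clean, tc, lc)

  cnn_fit <- train_cnn(build_default_cnn(), data$noisy, data$clean, tc, lc)

  eval_cfg <- synthetic_config(
    rate = synth$rate, duration = eval_duration, f0 = synth$f0,
    n_harmonics = synth$n_harmonics, amplitude = synth$amplitude,
    segments = default_segments(eval_duration), onset_ms = synth$onset_ms,
    unvoiced_gain = synth$unvoiced_gain,
    hf_noise_sigma = synth$hf_noise_sigma, lf_amp = synth$lf_amp,
    lf_freq = synth$lf_freq, channel_gains = synth$channel_gains,
    jitter = synth$jitter, seed = synth$seed + 1000L)
  rec <- synthesize_recording(eval_cfg)

  den_dbn <- denoise_pipeline(dbn_fit$model, rec$noisy, cfg)
  den_cnn <- denoise_pipeline(cnn_fit$weights, rec$noisy, cfg)

  reports <- list(
    CNN = evaluate_denoising(rec$clean, den_cnn, cfg$lne_frame,
                             cfg$score_weights),
    `Adam-DBNs` = evaluate_denoising(rec$clean, den_dbn, cfg$lne_frame,
                                     cfg$score_weights))
  list(table = comparison_table(reports), reports = reports,
       histories = list(dbn = dbn_fit$history, cnn = cnn_fit$history),
       models = list(dbn = dbn_fit$model, cnn = cnn_fit$weights),
       signals = list(clean = rec$clean, noisy = rec$noisy,
                      dbn = den_dbn, cnn = den_cnn))
}
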