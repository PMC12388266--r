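#' One-dimensional convolutional encoder-decoder comparator
#'
#' The baseline denoiser: a stack of stride-1 same-padded convolutions with
#' 2x max pooling on the way down, a sigmoid attention gate at the
#' bottleneck, nearest-neighbour-upsample-plus-convolution "deconvolutions"
#' on the way up, and a skip connection that projects the first convolution's
#' feature map through a short kernel and adds it after the last
#' deconvolution. A final length-1 projection reduces the features to a
#' single output channel so the network maps a window to a window. It shares
#' the joint loss, the Adam optimizer and the training loop with the DBN so
#' the two models can be compared under identical conditions.
#'
#' @name baseline_cnn
NULL

cnn_layer <- function(kind, kernel = NA_integer_, channels = NA_integer_,
                      activation = "none") {
  list(kind = kind, kernel = as.integer(kernel),
       channels = as.integer(channels), activation = activation)
}

#' Default CNN architecture
#'
#' The nine-stage stack used for comparisons: conv 15/64/ReLU, pool 2,
#' conv 11/128/ReLU, pool 2, conv 7/256/ReLU, attention 1/256/sigmoid,
#' deconv 5/128/ReLU, deconv 7/64/ReLU, skip 3.
#'
#' @return a `cnn_spec`: ordered list of layer descriptors.
#' @export
build_default_cnn <- function() {
  structure(list(
    cnn_layer("conv", 15L, 64L, "relu"),
    cnn_layer("pool", 2L),
    cnn_layer("conv", 11L, 128L, "relu"),
    cnn_layer("pool", 2L),
    cnn_layer("conv", 7L, 256L, "relu"),
    cnn_layer("attention", 1L, 256L, "sigmoid"),
    cnn_layer("deconv", 5L, 128L, "relu"),
    cnn_layer("deconv", 7L, 64L, "relu"),
    cnn_layer("skip", 3L)
  ), class = "cnn_spec")
}

validate_cnn_spec <- function(spec) {
  stopifnot(inherits(spec, "cnn_spec") || is.list(spec))
  kinds <- vapply(spec, `[[`, "", "kind")
  if (kinds[1L] != "conv")
    stop("the first CNN layer must be a convolution (the skip source)",
         call. = FALSE)
  if (sum(kinds == "pool") != sum(kinds == "deconv"))
    stop("pool and deconv counts must match for the output length to equal the input length",
         call. = FALSE)
  for (l in spec) {
    if (l$kind %in% c("conv", "deconv", "attention", "skip")) {
      if (l$kernel %% 2L == 0L)
        stop(sprintf("kernel length %d must be odd for same-padding", l$kernel),
             call. = FALSE)
    }
    if (l$kind %in% c("conv", "deconv", "attention") && l$channels < 1L)
      stop("channel counts must be positive", call. = FALSE)
  }
  invisible(spec)
}

#' Initialize CNN weights
#'
#' Seeded Gaussian initialization with fan-in scaling; biases start at zero.
#'
#' @param spec a `cnn_spec` (see [build_default_cnn()]).
#' @param input_channels channels of the input signal (1 for a raw window).
#' @param seed integer seed.
#' @return a `cnn_weights` object (list of `W`/`b` per parameterized stage,
#'   plus the final single-channel projection) with the spec attached.
#' @export
cnn_init <- function(spec = build_default_cnn(), input_channels = 1L,
                     seed = 42L) {
  validate_cnn_spec(spec)
  set.seed(seed)
  make_w <- function(k, c_in, c_out) {
    list(W = matrix(stats::rnorm(k * c_in * c_out, sd = 1 / sqrt(k * c_in)),
                    k * c_in, c_out),
         b = numeric(c_out))
  }
  weights <- list()
  c_cur <- as.integer(input_channels)
  c_first <- NA_integer_
  for (i in seq_along(spec)) {
    l <- spec[[i]]
    nm <- paste0("layer", i)
    if (l$kind %in% c("conv", "deconv")) {
      weights[[nm]] <- make_w(l$kernel, c_cur, l$channels)
      c_cur <- l$channels
      if (is.na(c_first)) c_first <- c_cur
    } else if (l$kind == "attention") {
      if (l$channels != c_cur)
        stop("attention channel count must match its input", call. = FALSE)
      weights[[nm]] <- make_w(l$kernel, c_cur, c_cur)
    } else if (l$kind == "skip") {
      weights[[nm]] <- make_w(l$kernel, c_first, c_cur)
    }
  }
  weights$proj <- make_w(1L, c_cur, 1L)
  structure(weights, class = "cnn_weights", spec = spec)
}

# --- array helpers: activations are (time, channel, batch) arrays ---------

flat_tb <- function(A) {            # (T, C, B) -> (T*B, C)
  d <- dim(A)
  M <- aperm(A, c(1L, 3L, 2L))
  dim(M) <- c(d[1L] * d[3L], d[2L])
  M
}

unflat_tb <- function(M, T_len, C, B) {   # inverse of flat_tb
  dim(M) <- c(T_len, B, C)
  aperm(M, c(1L, 3L, 2L))
}

# Row-shift bookkeeping for same-padded im2col: for kernel offset d, the
# destination rows (t) take source rows (t + d) within each batch block.
shift_rows <- function(T_len, B, d) {
  t_dest <- seq.int(max(1L, 1L - d), min(T_len, T_len - d))
  if (!length(t_dest)) return(NULL)
  block <- rep((seq_len(B) - 1L) * T_len, each = length(t_dest))
  list(dest = rep(t_dest, times = B) + block,
       src = rep(t_dest + d, times = B) + block)
}

im2col <- function(A, k) {
  d <- dim(A); T_len <- d[1L]; C <- d[2L]; B <- d[3L]
  p <- (k - 1L) %/% 2L
  M <- flat_tb(A)
  cols <- matrix(0, T_len * B, k * C)
  for (j in seq_len(k)) {
    off <- j - p - 1L
    sh <- shift_rows(T_len, B, off)
    if (!is.null(sh))
      cols[sh$dest, ((j - 1L) * C + 1L):(j * C)] <- M[sh$src, , drop = FALSE]
  }
  cols
}

col2im_grad <- function(dcols, k, T_len, C, B) {
  p <- (k - 1L) %/% 2L
  dM <- matrix(0, T_len * B, C)
  for (j in seq_len(k)) {
    off <- j - p - 1L
    sh <- shift_rows(T_len, B, off)
    if (!is.null(sh)) {
      blk <- dcols[sh$dest, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
      dM[sh$src, ] <- dM[sh$src, , drop = FALSE] + blk
    }
  }
  unflat_tb(dM, T_len, C, B)
}

conv_forward <- function(A, wts, k, activation = "none") {
  d <- dim(A)
  cols <- im2col(A, k)
  Z <- cols %*% wts$W
  Z <- Z + rep(wts$b, each = nrow(Z))
  out <- switch(activation,
                relu = pmax(Z, 0),
                sigmoid = sigmoid(Z),
                none = Z)
  list(out = unflat_tb(out, d[1L], ncol(wts$W), d[3L]),
       cols = cols, pre = Z, act = activation,
       in_dim = d)
}

conv_backward <- function(cache, wts, dOut) {
  dZ <- flat_tb(dOut)
  if (cache$act == "relu") {
    dZ <- dZ * (cache$pre > 0)
  } else if (cache$act == "sigmoid") {
    s <- sigmoid(cache$pre)
    dZ <- dZ * s * (1 - s)
  }
  k <- nrow(wts$W) / cache$in_dim[2L]
  list(dW = crossprod(cache$cols, dZ),
       db = colSums(dZ),
       dA = col2im_grad(dZ %*% t(wts$W), as.integer(k),
                        cache$in_dim[1L], cache$in_dim[2L], cache$in_dim[3L]))
}

pool_forward <- function(A) {
  d <- dim(A)
  if (d[1L] %% 2L != 0L) stop("pooling requires an even length", call. = FALSE)
  A1 <- A[seq.int(1L, d[1L], 2L), , , drop = FALSE]
  A2 <- A[seq.int(2L, d[1L], 2L), , , drop = FALSE]
  take_first <- A1 >= A2
  list(out = pmax(A1, A2), take_first = take_first, in_len = d[1L])
}

pool_backward <- function(cache, dOut) {
  d <- dim(dOut)
  dA <- array(0, dim = c(cache$in_len, d[2L], d[3L]))
  dA[seq.int(1L, cache$in_len, 2L), , ] <- dOut * cache$take_first
  dA[seq.int(2L, cache$in_len, 2L), , ] <- dOut * !cache$take_first
  dA
}

upsample2 <- function(A) {
  d <- dim(A)
  U <- array(0, dim = c(2L * d[1L], d[2L], d[3L]))
  U[seq.int(1L, 2L * d[1L], 2L), , ] <- A
  U[seq.int(2L, 2L * d[1L], 2L), , ] <- A
  U
}

downsample_grad2 <- function(dU) {
  d <- dim(dU)
  dU[seq.int(1L, d[1L], 2L), , , drop = FALSE] +
    dU[seq.int(2L, d[1L], 2L), , , drop = FALSE]
}

#' CNN forward pass
#'
#' @param weights a [cnn_init()] weight set (the spec travels with it).
#' @param x input window(s): numeric vector or `L x n` matrix. Lengths not
#'   divisible by the total pooling factor are zero-padded internally and the
#'   output is trimmed back, so the output shape always equals the input
#'   shape.
#' @param keep_cache internal: retain activations for backpropagation.
#' @return reconstruction of the same shape as `x`.
#' @export
cnn_forward <- function(weights, x, keep_cache = FALSE) {
  stopifnot(inherits(weights, "cnn_weights"))
  spec <- attr(weights, "spec")
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  T_in <- nrow(X); B <- ncol(X)
  factor_ <- 2L^sum(vapply(spec, `[[`, "", "kind") == "pool")
  T_pad <- as.integer(ceiling(T_in / factor_) * factor_)
  A <- array(0, dim = c(T_pad, 1L, B))
  A[seq_len(T_in), 1L, ] <- X
  caches <- vector("list", length(spec))
  skip_src <- NULL
  for (i in seq_along(spec)) {
    l <- spec[[i]]
    nm <- paste0("layer", i)
    if (l$kind == "conv") {
      cc <- conv_forward(A, weights[[nm]], l$kernel, l$activation)
      A <- cc$out
      if (is.null(skip_src)) skip_src <- list(idx = i, out = A)
      caches[[i]] <- cc
    } else if (l$kind == "pool") {
      cc <- pool_forward(A)
      A <- cc$out
      caches[[i]] <- cc
    } else if (l$kind == "attention") {
      cc <- conv_forward(A, weights[[nm]], l$kernel, "sigmoid")
      caches[[i]] <- c(cc, list(input = A))
      A <- A * cc$out
    } else if (l$kind == "deconv") {
      U <- upsample2(A)
      cc <- conv_forward(U, weights[[nm]], l$kernel, l$activation)
      A <- cc$out
      caches[[i]] <- cc
    } else if (l$kind == "skip") {
      cc <- conv_forward(skip_src$out, weights[[nm]], l$kernel, "none")
      A <- A + cc$out
      caches[[i]] <- cc
    }
  }
  pc <- conv_forward(A, weights$proj, 1L, "none")
  out_full <- matrix(pc$out[, 1L, ], nrow = T_pad, ncol = B)
  out <- out_full[seq_len(T_in), , drop = FALSE]
  res <- if (is.matrix(x)) out else drop(out)
  if (!keep_cache) return(res)
  list(out = out, caches = caches, proj_cache = pc, skip_idx = skip_src$idx,
       T_in = T_in, T_pad = T_pad, B = B)
}

# Backpropagate dL/dout (T_in x B matrix) through the whole network.
cnn_backward <- function(weights, fwd, G) {
  spec <- attr(weights, "spec")
  grads <- lapply(weights, function(w) list(dW = 0 * w$W, db = 0 * w$b))
  dOut <- array(0, dim = c(fwd$T_pad, 1L, fwd$B))
  dOut[seq_len(fwd$T_in), 1L, ] <- G
  pb <- conv_backward(fwd$proj_cache, weights$proj, dOut)
  grads$proj$dW <- pb$dW; grads$proj$db <- pb$db
  dA <- pb$dA
  d_skip_src <- NULL
  for (i in rev(seq_along(spec))) {
    l <- spec[[i]]
    nm <- paste0("layer", i)
    cc <- fwd$caches[[i]]
    if (l$kind == "skip") {
      sb <- conv_backward(cc, weights[[nm]], dA)
      grads[[nm]]$dW <- sb$dW; grads[[nm]]$db <- sb$db
      d_skip_src <- sb$dA          # flows to the first conv's output
      # dA continues unchanged into the main branch
    } else if (l$kind == "deconv") {
      cb <- conv_backward(cc, weights[[nm]], dA)
      grads[[nm]]$dW <- cb$dW; grads[[nm]]$db <- cb$db
      dA <- downsample_grad2(cb$dA)
    } else if (l$kind == "attention") {
      gate <- cc$out
      dGate <- dA * cc$input
      dInput_direct <- dA * gate
      ab <- conv_backward(cc[names(cc) != "input"], weights[[nm]], dGate)
      grads[[nm]]$dW <- ab$dW; grads[[nm]]$db <- ab$db
      dA <- dInput_direct + ab$dA
    } else if (l$kind == "pool") {
      dA <- pool_backward(cc, dA)
    } else if (l$kind == "conv") {
      if (!is.null(d_skip_src) && i == fwd$skip_idx) {
        dA <- dA + d_skip_src
        d_skip_src <- NULL
      }
      cb <- conv_backward(cc, weights[[nm]], dA)
      grads[[nm]]$dW <- cb$dW; grads[[nm]]$db <- cb$db
      dA <- cb$dA
    }
  }
  grads
}

#' Train the CNN comparator
#'
#' Shares [adam_step()], [joint_loss()], the learning-rate schedule, and the
#' training loop with [fine_tune()], so a DBN-vs-CNN comparison differs only
#' in the model.
#'
#' @param spec a `cnn_spec`; the default Table-style stack via
#'   [build_default_cnn()].
#' @param noisy,clean paired window batches (`L x n` matrices).
#' @param cfg a [train_config()].
#' @param loss_cfg a [loss_config()].
#' @param weights optional pre-initialized [cnn_init()] weights.
#' @return `list(weights, history)` analogous to [fine_tune()].
#' @export
train_cnn <- function(spec = build_default_cnn(), noisy, clean,
                      cfg = train_config(), loss_cfg = loss_config(),
                      weights = NULL) {
  if (is.null(weights)) weights <- cnn_init(spec, seed = cfg$seed)
  template <- weights
  strip <- function(w) lapply(unclass(w), function(l) list(W = l$W, b = l$b))
  rebuild <- function(params) {
    out <- template
    for (nm in names(params)) {
      out[[nm]]$W <- params[[nm]]$W
      out[[nm]]$b <- params[[nm]]$b
    }
    out
  }
  fit <- run_supervised_training(
    strip(weights),
    forward = function(params, V) {
      fwd <- cnn_forward(rebuild(params), V, keep_cache = TRUE)
      fwd
    },
    backward = function(params, fwd, G) {
      g <- cnn_backward(rebuild(params), fwd, G)
      lapply(g, function(l) list(W = l$dW, b = l$db))
    },
    noisy = noisy, clean = clean, cfg = cfg, loss_cfg = loss_cfg)
  list(weights = rebuild(fit$params), history = fit$history)
}

#' @rdname denoise
#' @param chunk number of windows processed per CNN batch (memory bound).
#' @export
denoise.cnn_weights <- function(model, x, L = 64L, chunk = 256L) {
  denoise_windows(function(V) {
    K <- ncol(V)
    out <- matrix(0, nrow(V), K)
    for (start in seq(1L, K, by = chunk)) {
      idx <- start:min(start + chunk - 1L, K)
      out[, idx] <- cnn_forward(model, V[, idx, drop = FALSE])
    }
    out
  }, x, L)
}
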