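#' AK-DL architecture configuration
#'
#' Architecture constants of the AK-DL shallow network: a LeNet-style stack
#' of two 5x5 convolutions (6 and 16 filters, stride 1, padding 2) with a
#' single 2x2 max pooling layer after the first convolution, followed by a
#' fully connected hidden layer, dropout, and a 2-unit softmax head.
#' LeakyReLU (slope 0.01) is the activation throughout.
#'
#' @param input_size side length of the square RGB input (default 64).
#' @param kernel_size convolution kernel side (default 5).
#' @param conv_stride convolution stride (default 1; the only supported
#'   value).
#' @param conv_padding zero padding (default 2, preserving spatial size
#'   with the default kernel).
#' @param filters integer vector of length 2: filters of the two
#'   convolutional layers (default `c(6, 16)`).
#' @param fc_width hidden units of the fully connected layer.  Default 120,
#'   inherited from the first fully connected layer of LeNet-5 from which
#'   the architecture is derived.
#' @param dropout_p dropout probability after the hidden layer, active only
#'   during training (default 0.5).
#' @param leaky_slope negative-half slope of LeakyReLU (default 0.01).
#' @param n_classes output units (default 2).
#' @param init_seed seed of the deterministic weight initialization.
#' @return An object of class `akdl_config`.
#' @export
akdl_config <- function(input_size = 64L, kernel_size = 5L,
                        conv_stride = 1L, conv_padding = 2L,
                        filters = c(6L, 16L), fc_width = 120L,
                        dropout_p = 0.5, leaky_slope = 0.01,
                        n_classes = 2L, init_seed = 1L) {
  check_scalar_num(input_size, "input_size", lower = 8, integer = TRUE)
  check_scalar_num(kernel_size, "kernel_size", lower = 1, integer = TRUE)
  if (!identical(as.integer(conv_stride), 1L))
    stop_config("conv_stride", "must be 1")
  check_scalar_num(conv_padding, "conv_padding", lower = 0, integer = TRUE)
  if (length(filters) != 2L || any(filters < 1))
    stop_config("filters", "must be two positive counts")
  check_scalar_num(fc_width, "fc_width", lower = 1, integer = TRUE)
  check_scalar_num(dropout_p, "dropout_p", lower = 0)
  if (dropout_p >= 1) stop_config("dropout_p", "must be < 1")
  check_scalar_num(leaky_slope, "leaky_slope")
  if (leaky_slope <= 0) stop_config("leaky_slope", "must be > 0")
  check_scalar_num(n_classes, "n_classes", lower = 2, integer = TRUE)
  check_scalar_num(init_seed, "init_seed", integer = TRUE)
  if (input_size %% 2L != 0L)
    stop_config("input_size", "must be even (one 2x2 pooling stage)")
  structure(list(input_size = as.integer(input_size),
                 kernel_size = as.integer(kernel_size),
                 conv_stride = 1L,
                 conv_padding = as.integer(conv_padding),
                 filters = as.integer(filters),
                 pool_window = 2L,
                 fc_width = as.integer(fc_width),
                 dropout_p = dropout_p,
                 leaky_slope = leaky_slope,
                 n_classes = as.integer(n_classes),
                 init_seed = as.integer(init_seed)),
            class = "akdl_config")
}

#' Training (optimizer) configuration
#'
#' Hyperparameters of the momentum SGD optimizer used to train AK-DL.  The
#' defaults are the published AK-DL settings: momentum 0.9, initial
#' learning rate 1e-4, mini-batch size 10, L2 regularization 5e-4.
#'
#' @param momentum classical momentum coefficient.
#' @param initial_learn_rate fixed learning rate.
#' @param mini_batch_size samples per mini-batch; the final partial batch
#'   of an epoch is used, not dropped.
#' @param l2_regularization weight-decay coefficient applied to weights
#'   (not biases).
#' @param epochs number of training epochs (default 30).
#' @param shuffle_seed seed of the epoch shuffling and dropout stream.
#' @return An object of class `train_config`.
#' @export
train_config <- function(momentum = 0.9, initial_learn_rate = 1e-4,
                         mini_batch_size = 10L, l2_regularization = 5e-4,
                         epochs = 30L, shuffle_seed = 1L) {
  check_scalar_num(momentum, "momentum", lower = 0)
  check_scalar_num(initial_learn_rate, "initial_learn_rate", lower = 0)
  check_scalar_num(mini_batch_size, "mini_batch_size", lower = 1,
                   integer = TRUE)
  check_scalar_num(l2_regularization, "l2_regularization", lower = 0)
  check_scalar_num(epochs, "epochs", lower = 1, integer = TRUE)
  check_scalar_num(shuffle_seed, "shuffle_seed", integer = TRUE)
  structure(list(momentum = momentum,
                 initial_learn_rate = initial_learn_rate,
                 mini_batch_size = as.integer(mini_batch_size),
                 l2_regularization = l2_regularization,
                 epochs = as.integer(epochs),
                 shuffle_seed = as.integer(shuffle_seed)),
            class = "train_config")
}

#' Intermediate tensor shapes of the network
#'
#' @param config an [akdl_config()].
#' @return Named list of dimension vectors: after conv1, after pooling,
#'   after conv2, and the flattened length feeding the fully connected
#'   layer.
#' @export
model_shapes <- function(config = akdl_config()) {
  s <- config$input_size
  # stride-1 "same" convolution: out = in + 2*pad - k + 1
  s1 <- s + 2L * config$conv_padding - config$kernel_size + 1L
  sp <- s1 %/% 2L
  s2 <- sp + 2L * config$conv_padding - config$kernel_size + 1L
  list(conv1 = c(s1, s1, config$filters[1]),
       pool = c(sp, sp, config$filters[1]),
       conv2 = c(s2, s2, config$filters[2]),
       flatten = s2 * s2 * config$filters[2])
}

# Seeded He-uniform fan-in initialization, the standard scheme for
# ReLU-family activations: U(-sqrt(6/fan_in), sqrt(6/fan_in)) for weights,
# zeros for biases.  Draw order is fixed, so init_seed fully determines
# the weights.  Values are rounded to float32, the precision at which the
# network stores and trains its parameters.
init_weights <- function(config) {
  k <- config$kernel_size
  f <- config$filters
  shp <- model_shapes(config)
  with_seed(config$init_seed, {
    u <- function(dims, fan_in) {
      lim <- sqrt(6 / fan_in)
      cpp_float_round(array(runif(prod(dims), -lim, lim), dim = dims))
    }
    list(W1 = u(c(k, k, 3L, f[1]), k * k * 3),
         b1 = numeric(f[1]),
         W2 = u(c(k, k, f[1], f[2]), k * k * f[1]),
         b2 = numeric(f[2]),
         W3 = u(c(config$fc_width, shp$flatten), shp$flatten),
         b3 = numeric(config$fc_width),
         W4 = u(c(config$n_classes, config$fc_width), config$fc_width),
         b4 = numeric(config$n_classes))
  })
}

#' Build an untrained AK-DL model
#'
#' Constructs the network with deterministically initialized weights
#' (seeded uniform fan-in scheme, zero biases).  The result can be
#' inspected, scored as-is, or trained with [akdl()].
#'
#' @param config an [akdl_config()].
#' @return An object of class `akdl` with empty training history.
#' @examples
#' m <- akdl_build(akdl_config())
#' count_parameters(m)
#' @export
akdl_build <- function(config = akdl_config()) {
  structure(list(weights = init_weights(config), config = config,
                 control = NULL, history = NULL,
                 input_space = "lab", call = sys.call()),
            class = "akdl")
}

#' Count trainable parameters
#'
#' @param model an `akdl` model.
#' @return Exact number of trainable scalars, biases included.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "akdl"))
  sum(vapply(model$weights, length, integer(1)))
}

leaky <- function(z, slope) {
  neg <- z < 0
  z[neg] <- z[neg] * slope
  z
}

leaky_grad <- function(z, slope) {
  g <- array(1, dim = dim(z))
  g[z < 0] <- slope
  g
}

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# Forward pass over a batch tensor x (s, s, 3, B).  When training = TRUE a
# dropout mask is drawn from the current RNG stream (inverted dropout, so
# inference needs no rescaling).  Returns probabilities (B x n_classes,
# column j = class j - 1) and, if keep_cache, the intermediates backprop
# needs.  Activations are applied in place on freshly allocated buffers;
# LeakyReLU preserves sign (slope > 0) so its derivative is recovered from
# the activated values and pre-activations need not be kept.
forward_akdl <- function(w, x, config, training = FALSE,
                         keep_cache = FALSE) {
  slope <- config$leaky_slope
  pad <- config$conv_padding
  B <- dim(x)[4]
  c1 <- cpp_conv2d_forward(x, w$W1, w$b1, pad, keep_patches = keep_cache)
  a1 <- cpp_leaky_inplace(c1$y, slope)
  pl <- cpp_maxpool_forward(a1)
  c2 <- cpp_conv2d_forward(pl$y, w$W2, w$b2, pad,
                           keep_patches = keep_cache)
  a2 <- cpp_leaky_inplace(c2$y, slope)
  fm <- matrix(a2, ncol = B)                      # flatten, column-major
  a3 <- leaky(w$W3 %*% fm + w$b3, slope)
  mask <- NULL
  a3d <- a3
  if (training && config$dropout_p > 0) {
    mask <- array(runif(length(a3)) >= config$dropout_p, dim = dim(a3))
    a3d <- a3 * mask / (1 - config$dropout_p)
  }
  z4 <- w$W4 %*% a3d + w$b4
  probs <- t(softmax_cols(z4))
  if (!keep_cache) return(list(probs = probs))
  list(probs = probs,
       cache = list(x = x, a1 = a1, pool = pl, fm = fm, a3 = a3,
                    a3d = a3d, mask = mask,
                    patches1 = c1$patches, patches2 = c2$patches))
}

# Gradient of mean cross-entropy w.r.t. all weights for one batch.
backward_akdl <- function(w, cache, probs, y, config) {
  slope <- config$leaky_slope
  pad <- config$conv_padding
  B <- length(y)
  onehot <- matrix(0, nrow = config$n_classes, ncol = B)
  onehot[cbind(y + 1L, seq_len(B))] <- 1
  dz4 <- (t(probs) - onehot) / B
  dW4 <- tcrossprod(dz4, cache$a3d)
  db4 <- rowSums(dz4)
  da3d <- crossprod(w$W4, dz4)
  da3 <- if (is.null(cache$mask)) da3d else
    da3d * cache$mask / (1 - config$dropout_p)
  dz3 <- da3 * leaky_grad(cache$a3, slope)
  dW3 <- tcrossprod(dz3, cache$fm)
  db3 <- rowSums(dz3)
  dz2 <- crossprod(w$W3, dz3)                     # gradient w.r.t. fm
  dp <- dim(cache$pool$y)
  dim(dz2) <- c(dp[1], dp[2], dim(w$W2)[4], dp[4])
  dz2 <- cpp_leaky_grad_inplace(dz2, cache$fm, slope)
  g2 <- cpp_conv2d_backward(cache$pool$y, w$W2, dz2, pad,
                            patches = cache$patches2)
  da1 <- cpp_maxpool_backward(g2$dx, cache$pool$argmax, dim(cache$a1))
  dz1 <- cpp_leaky_grad_inplace(da1, cache$a1, slope)
  g1 <- cpp_conv2d_backward(cache$x, w$W1, dz1, pad, need_dx = FALSE,
                            patches = cache$patches1)
  list(W1 = g1$dw, b1 = g1$db, W2 = g2$dw, b2 = g2$db,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
}

check_input_tensor <- function(x, config) {
  d <- dim(x)
  s <- config$input_size
  if (is.null(d) || length(d) != 4L || d[1] != s || d[2] != s || d[3] != 3L)
    stop(sprintf("input tensor must be %d x %d x 3 x n", s, s),
         call. = FALSE)
  if (min(x) < 0 || max(x) > 1)
    stop("input tensor values must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

#' Fit the AK-DL shallow convolutional network
#'
#' Trains the two-convolution network on standardized `64 x 64 x 3` inputs
#' with mini-batch stochastic gradient descent using classical momentum,
#' a fixed learning rate, L2 weight decay on weights (not biases) and
#' cross-entropy loss on the softmax output.  Dropout is active only
#' during training.  Training is fully deterministic given
#' `config$init_seed`, `control$shuffle_seed` and the data.
#'
#' @param x either an [image_set] (preprocessed internally via `plan`) or a
#'   numeric `s x s x 3 x n` tensor in `[0, 1]` as produced by
#'   [preprocess_set()].
#' @param y integer 0/1 labels (required when `x` is a tensor; ignored
#'   otherwise).
#' @param config an [akdl_config()].
#' @param control a [train_config()].
#' @param plan a [preprocess_plan()] used when `x` is an [image_set].
#' @param augment apply augmentation during internal preprocessing
#'   (only meaningful when `x` is an [image_set]).
#' @return An object of class `akdl`: weights, configurations, and a
#'   training history with one row per epoch (`loss` = mean cross-entropy
#'   over the epoch's training-mode batches; `accuracy` = running accuracy
#'   of those same forward passes).
#' @seealso [predict.akdl()], [akdl_build()], [count_parameters()]
#' @export
akdl <- function(x, y = NULL, config = akdl_config(),
                 control = train_config(), plan = preprocess_plan(),
                 augment = FALSE) {
  cl <- match.call()
  input_space <- plan$input_space
  if (inherits(x, "image_set")) {
    pp <- preprocess_set(x, plan, augment = augment)
    x <- pp$x
    y <- pp$y
  }
  if (is.null(y)) stop("labels 'y' are required", call. = FALSE)
  y <- as.integer(y)
  check_input_tensor(x, config)
  n <- dim(x)[4]
  if (length(y) != n)
    stop("length of 'y' must match the number of input samples",
         call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training data contains a single class; both classes required",
         call. = FALSE)

  w <- init_weights(config)
  # the shuffle seed drives one RNG stream producing, per epoch, the
  # sample order and then the uniforms behind the dropout masks (consumed
  # batch-by-batch in slot order); training is a pure function of
  # (weights, data, these streams)
  epochs <- control$epochs
  orders <- vector("list", epochs)
  dropu <- vector("list", epochs)
  with_seed(control$shuffle_seed, {
    for (ep in seq_len(epochs)) {
      orders[[ep]] <- sample.int(n)
      if (config$dropout_p > 0)
        dropu[[ep]] <- runif(config$fc_width * n)
    }
  })
  res <- cpp_akdl_train(x, y, w, unclass(config), unclass(control),
                        orders, dropu)

  structure(list(weights = res$weights, config = config,
                 control = control,
                 history = data.frame(epoch = seq_len(epochs),
                                      loss = res$loss,
                                      accuracy = res$accuracy),
                 input_space = input_space, call = cl),
            class = "akdl")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict class probabilities or labels from an AK-DL model
#'
#' Inference runs with dropout disabled and is deterministic given the
#' weights.  Each probability row sums to one.
#'
#' @param object an `akdl` model.
#' @param newdata an [image_set] (preprocessed with the plan implied by the
#'   model's `input_space`) or a standardized `s x s x 3 x n` tensor.
#' @param type `"prob"` for an `n x 2` matrix with columns `bk` and `ak`,
#'   or `"class"` for 0/1 labels at the 0.5 threshold on the AK
#'   probability.
#' @param ... ignored.
#' @return Probability matrix or integer label vector.
#' @export
predict.akdl <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "image_set")) {
    plan <- preprocess_plan(input_space = object$input_space,
                            target_size = object$config$input_size)
    newdata <- preprocess_set(newdata, plan)$x
  }
  check_input_tensor(newdata, object$config)
  probs <- forward_akdl(object$weights, newdata, object$config,
                        training = FALSE)$probs
  colnames(probs) <- c("bk", "ak")
  if (type == "prob") probs else as.integer(probs[, "ak"] >= 0.5)
}

#' @export
print.akdl <- function(x, ...) {
  shp <- model_shapes(x$config)
  cat("AK-DL shallow convolutional network\n")
  cat(sprintf("  input %dx%dx3 -> conv(%d@%dx%d) -> pool -> conv(%d@%dx%d) -> fc(%d) -> dropout(%.2f) -> %d classes\n",
              x$config$input_size, x$config$input_size,
              x$config$filters[1], x$config$kernel_size,
              x$config$kernel_size, x$config$filters[2],
              x$config$kernel_size, x$config$kernel_size,
              x$config$fc_width, x$config$dropout_p, x$config$n_classes))
  cat(sprintf("  parameters: %d; input space: %s\n",
              count_parameters(x), x$input_space))
  if (is.null(x$history)) {
    cat("  untrained (seeded initialization only)\n")
  } else {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; final loss %.4f, training accuracy %.3f\n",
                nrow(x$history), last$loss, last$accuracy))
  }
  invisible(x)
}

#' @export
summary.akdl <- function(object, ...) {
  print(object)
  shp <- model_shapes(object$config)
  cat("\nShape chain:\n")
  cat(sprintf("  conv1: %s\n", paste(shp$conv1, collapse = "x")))
  cat(sprintf("  pool : %s\n", paste(shp$pool, collapse = "x")))
  cat(sprintf("  conv2: %s\n", paste(shp$conv2, collapse = "x")))
  cat(sprintf("  flatten: %d\n", shp$flatten))
  cat("\nParameters per layer:\n")
  for (nm in names(object$weights))
    cat(sprintf("  %s: %d\n", nm, length(object$weights[[nm]])))
  invisible(object)
}

#' @export
coef.akdl <- function(object, ...) object$weights

#' Plot the training history of an AK-DL model
#'
#' @param x a trained `akdl` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.akdl <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history",
                               call. = FALSE)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$history$epoch, x$history$loss, type = "l",
                 xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::plot(x$history$epoch, x$history$accuracy, type = "l",
                 xlab = "epoch", ylab = "training accuracy", ylim = c(0, 1),
                 ...)
  invisible(x)
}

#' Save / load an AK-DL model
#'
#' The model is written as an RDS checkpoint next to a sidecar JSON file
#' (`<path>.json`) recording the architecture and training configurations
#' for reproducibility.
#'
#' @param model an `akdl` model.
#' @param path checkpoint file path.
#' @return `save_akdl` returns `path` invisibly; `load_akdl` returns the
#'   model.
#' @export
save_akdl <- function(model, path) {
  stopifnot(inherits(model, "akdl"))
  saveRDS(model, path)
  sidecar <- list(config = unclass(model$config),
                  control = if (!is.null(model$control))
                    unclass(model$control),
                  input_space = model$input_space)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_akdl
#' @export
load_akdl <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "akdl"))
  m
}
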