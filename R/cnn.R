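# R interface to the 1D convolutional regressor.

#' Configuration of the convolutional joint-angle regressor
#'
#' The default configuration is the compact Conv1D network used for
#' single-channel window regression: four valid-padding convolutions
#' (50, 50, 100, 100 filters, kernel 3, stride 1) with 2:1 max pooling
#' after the second, a 100-unit dense ReLU layer and a linear output,
#' trained with Adam (learning rate 0.001) on mean squared error for 50
#' epochs at batch size 512, weights drawn from the Glorot-normal
#' initializer.
#'
#' @param input_len Window length in samples (60 = 0.6 s at 100 Hz).
#' @param conv_filters Filter counts of the four convolution layers.
#' @param kernel_size,pool_size Kernel length and pooling factor.
#' @param dense_units Width of the hidden dense layer.
#' @param learning_rate,batch_size,epochs Adam training recipe.
#' @param rng_seed Seed for weight initialisation and batch shuffling.
#' @return A `cnn_config` list.
#' @export
#' @examples
#' cnn_shape_trace(cnn_config())
cnn_config <- function(input_len = 60L, conv_filters = c(50L, 50L, 100L, 100L),
                       kernel_size = 3L, pool_size = 2L, dense_units = 100L,
                       learning_rate = 0.001, batch_size = 512L,
                       epochs = 50L, rng_seed = 1L) {
  if (length(conv_filters) != 4L || any(conv_filters < 1)) {
    stop_arg("conv_filters must be four positive counts")
  }
  cfg <- structure(
    list(input_len = as.integer(input_len),
         conv_filters = as.integer(conv_filters),
         kernel_size = as.integer(kernel_size),
         pool_size = as.integer(pool_size),
         dense_units = as.integer(dense_units),
         learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         epochs = as.integer(epochs),
         rng_seed = as.integer(rng_seed)),
    class = "cnn_config"
  )
  cnn_shape_trace(cfg)  # validates the kernel chain
  cfg
}

#' Layer-by-layer output shapes of the network
#'
#' Computes the feature length after every layer for a given
#' configuration; with the defaults on a 60-sample input the lengths
#' run 58, 56, 28, 26, 24, a flattened size of 2400, then 100 and 1.
#'
#' @param config A [cnn_config()].
#' @return A tibble with columns `layer`, `output_len` and `channels`.
#' @export
cnn_shape_trace <- function(config = cnn_config()) {
  k <- config$kernel_size
  f <- config$conv_filters
  l1 <- config$input_len - k + 1L
  l2 <- l1 - k + 1L
  if (l2 < config$pool_size || l2 %% config$pool_size != 0L) {
    stop_arg("second conv output length %d is not divisible by pool size %d",
             l2, config$pool_size)
  }
  lp <- l2 %/% config$pool_size
  l3 <- lp - k + 1L
  l4 <- l3 - k + 1L
  if (l4 < 1L) {
    stop_arg("input length %d is too short for the kernel chain",
             config$input_len)
  }
  tibble(
    layer = c("input", "conv1", "conv2", "maxpool", "conv3", "conv4",
              "flatten", "dense", "output"),
    output_len = c(config$input_len, l1, l2, lp, l3, l4,
                   l4 * f[4], config$dense_units, 1L),
    channels = c(1L, f[1], f[2], f[2], f[3], f[4], 1L, 1L, 1L)
  )
}

#' Fit the convolutional regressor on a frame set
#'
#' Runs the fixed training recipe (no validation split or early
#' stopping): `epochs` passes of Adam over uniformly shuffled batches,
#' partial final batch included. Deterministic given `rng_seed`.
#'
#' @param frames A `frame_set` from [make_frames()] or
#'   [bind_frame_sets()].
#' @param config A [cnn_config()].
#' @return A `cnn_fit` object holding the trained weights, the
#'   per-epoch training loss and the training manifest.
#' @export
fit_cnn <- function(frames, config = cnn_config()) {
  if (!inherits(frames, "frame_set")) stop_arg("frames must be a frame_set")
  if (n_frames(frames) == 0L) stop_arg("frame set is empty")
  if (ncol(frames$X) != config$input_len) {
    stop_arg("frames have %d samples but the network expects %d",
             ncol(frames$X), config$input_len)
  }
  res <- cnn_train_cpp(frames$X, frames$y, unclass(config))
  structure(
    list(config = config, weights = res$weights,
         training_history = as.numeric(res$history),
         joint = frames$joint, channel = frames$channel,
         manifest = frames$manifest),
    class = "cnn_fit"
  )
}

#' Predict angle values for a frame set
#'
#' @param object A `cnn_fit`.
#' @param frames A `frame_set` whose windows match the fitted input
#'   length.
#' @param ... Unused.
#' @return A tibble with `center_time` and `.pred` (degrees), ordered
#'   by centre time.
#' @export
predict.cnn_fit <- function(object, frames, ...) {
  if (!inherits(frames, "frame_set")) stop_arg("frames must be a frame_set")
  if (ncol(frames$X) != object$config$input_len) {
    stop_arg("frames have %d samples but the network expects %d",
             ncol(frames$X), object$config$input_len)
  }
  pred <- cnn_predict_cpp(object$weights, frames$X, unclass(object$config))
  ord <- order(frames$center_times)
  tibble(center_time = frames$center_times[ord], .pred = pred[ord])
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat(sprintf(
    "<cnn_fit> joint %s | channel %s | %d epochs | final loss %.4g\n",
    x$joint, x$channel, length(x$training_history),
    tail(x$training_history, 1)
  ))
  invisible(x)
}

#' Tidy the training history of a fitted network
#'
#' @param x A `cnn_fit`.
#' @param ... Unused.
#' @return A tibble with `epoch` and `loss` (training MSE, deg^2).
#' @exportS3Method
tidy.cnn_fit <- function(x, ...) {
  tibble(epoch = seq_along(x$training_history), loss = x$training_history)
}

#' One-row summary of a fitted network
#'
#' @param x A `cnn_fit`.
#' @param ... Unused.
#' @return A tibble with joint, channel, frame count, epochs and the
#'   first/final training loss.
#' @exportS3Method
glance.cnn_fit <- function(x, ...) {
  tibble(
    joint = x$joint, channel = x$channel,
    n_frames = sum(x$manifest$n),
    epochs = length(x$training_history),
    first_loss = x$training_history[1],
    final_loss = tail(x$training_history, 1)
  )
}

#' Plot the training-loss curve
#'
#' @param object A `cnn_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method
autoplot.cnn_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = expression(training~MSE~(deg^2)),
                  title = sprintf("%s / %s", object$joint, object$channel)) +
    ggplot2::theme_minimal()
}
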