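# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_arg <- function(msg, ...) abort(sprintf(msg, ...), class = "gaitcnn_argument_error")

stop_data <- function(msg, ...) abort(sprintf(msg, ...), class = "gaitcnn_data_error")

stop_metric <- function(msg, ...) abort(sprintf(msg, ...), class = "gaitcnn_metric_error")

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic stages (cohort sampling, session simulation, per-fold
#' network initialisation and batch shuffling) draw their seeds from one
#' master seed through this splitter, so a single integer reproduces an
#' entire study while keeping the streams of different stages decoupled.
#'
#' @param master_seed Integer master seed.
#' @param ... Integers or short strings identifying the consumer
#'   (e.g. a fold index, a channel name).
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(master_seed, ...) {
  parts <- list(...)
  h <- as.double(master_seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    for (v in as.double(p)) {
      h <- (h * 48271 + (v %% 2147483647) + 11) %% 2147483647
    }
  }
  as.integer(h)
}

# Strict interior local maxima of a numeric vector (indices).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

# Centred finite-difference derivative on a uniform grid.
num_deriv <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}
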