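# Brute-force re-implementations of the evaluation statistics,
# used as independent oracles against the package implementations.
brute_r2 <- function(y, yhat) {
  ss_res <- 0
  ss_tot <- 0
  m <- sum(y) / length(y)
  for (i in seq_along(y)) {
    ss_res <- ss_res + (y[i] - yhat[i])^2
    ss_tot <- ss_tot + (y[i] - m)^2
  }
  1 - ss_res / ss_tot
}
brute_rmse <- function(r) {
  s <- 0
  for (v in r) s <- s + v^2
  sqrt(s / length(r))
}
brute_sd <- function(r) {
  m <- sum(r) / length(r)
  s <- 0
  for (v in r) s <- s + (v - m)^2
  sqrt(s / (length(r) - 1))
}

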