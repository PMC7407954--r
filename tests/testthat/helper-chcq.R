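# Shared fixtures: tiny layer parameter blocks with known values, and an
# independently coded brute-force layer oracle used to cross-check the
# vectorized forward pass.

const_qlayer <- function(W, eps = 0 * W, theta = 0 * W) {
  structure(list(W = W, eps = eps, theta = theta), class = "qlayer")
}

# Brute-force re-implementation of the layer equations with explicit
# scalar loops and no shared code with layer_forward().
oracle_layer <- function(W, eps, theta, angles) {
  n_units <- ncol(W)
  y <- numeric(n_units)
  for (j in seq_len(n_units)) {
    re <- 0; im <- 0
    for (i in seq_len(nrow(W))) {
      re <- re + W[i, j] * cos(angles[i])
      im <- im + W[i, j] * sin(angles[i])
    }
    th <- mean(theta[, j])
    re <- re - cos(th); im <- im - sin(th)
    ep <- mean(eps[, j])
    y[j] <- (pi / 2) / (1 + exp(-ep)) - atan2(im, re)
  }
  list(y = y, a = sin(y)^2)
}

rand_qlayer <- function(n_in, n_units) {
  const_qlayer(matrix(runif(n_in * n_units, -1, 1), n_in, n_units),
               matrix(runif(n_in * n_units, -2, 2), n_in, n_units),
               matrix(runif(n_in * n_units, 0, 2 * pi), n_in, n_units))
}
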