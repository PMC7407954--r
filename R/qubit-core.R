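# Phase-encoded qubit-neuron arithmetic.
#
# A unit's state is a phase angle y; its two basis amplitudes are cos(y) and
# sin(y), and the probability of reading out the |1> state is sin^2(y).  All
# real-valued activations in the package (hidden representations and the
# conditioned response CR) are this |1>-state probability, so they live in
# [0, 1] by construction.

#' Unit phasor of a phase angle
#'
#' Maps a phase angle to the unit complex number `cos(theta) + i sin(theta)`.
#' This is the elementary "qubit state" used throughout the network: inputs,
#' thresholds and hidden states all enter the pre-activation sum as unit
#' phasors.
#'
#' @param theta Numeric vector of finite phase angles (radians).
#' @return Complex vector of modulus 1.
#' @examples
#' phasor(0)        # 1 + 0i
#' phasor(pi / 2)   # ~ 0 + 1i
#' @export
phasor <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta))) {
    stop("`theta` must be finite numeric", call. = FALSE)
  }
  complex(real = cos(theta), imaginary = sin(theta))
}

#' Logistic sigmoid
#'
#' `S(x) = 1 / (1 + exp(-x))`, the squashing applied to the reversal
#' parameter before it scales the pi/2 phase offset.
#'
#' @param x Numeric vector, finite.
#' @return Values in (0, 1).
#' @export
logsigmoid <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`x` must be finite numeric", call. = FALSE)
  }
  stats::plogis(x)
}

#' Encode a cue vector as phase angles
#'
#' Scales amplitudes in \[0, 1\] onto \[0, pi/2\], the quarter-circle of
#' admissible qubit phases (the role a Hadamard-style superposition plays
#' conceptually: amplitude 0 maps to the |0> phase, amplitude 1 to the |1>
#' phase, intermediate amplitudes to intermediate superpositions).
#'
#' @param p Numeric vector with every element in \[0, 1\].
#' @return Phase-angle vector `(pi/2) * p` in \[0, pi/2\].
#' @examples
#' encode_input(c(1, 0))    # pi/2, 0
#' encode_input(0.5)        # pi/4
#' @export
encode_input <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p))) {
    stop("cue amplitudes must be finite numeric", call. = FALSE)
  }
  bad <- which(p < 0 | p > 1)
  if (length(bad)) {
    stop("cue amplitude out of [0, 1] at index ", bad[1L],
         " (value ", format(p[bad[1L]]), ")", call. = FALSE)
  }
  (pi / 2) * p
}

#' Principal argument of a complex pre-activation
#'
#' Two-argument arctangent of the imaginary over the real part, returning a
#' phase in (-pi, pi].  A pre-activation with modulus below `tol` has no
#' defined phase; this signals a `chcq_degenerate` error carrying the unit
#' indices so a training loop can re-randomize the offending unit.
#'
#' @param v Complex vector.
#' @param tol Modulus below which the phase is considered undefined.
#' @return Numeric vector of principal arguments.
#' @export
complex_phase <- function(v, tol = 1e-12) {
  m <- Mod(v)
  if (any(m < tol)) {
    units <- which(m < tol)
    cond <- structure(
      class = c("chcq_degenerate", "error", "condition"),
      list(message = paste0("degenerate pre-activation (|v| < ", tol,
                            ") at unit(s) ", paste(units, collapse = ", ")),
           call = sys.call(-1), units = units))
    stop(cond)
  }
  atan2(Im(v), Re(v))
}

#' |1>-state readout probability
#'
#' `sin^2(y)`: the probability that the unit's qubit collapses to |1>.
#' Complements `cos^2(y)` so the two readout probabilities always sum to 1.
#'
#' @param y Numeric phase angle(s).
#' @return Values in \[0, 1\].
#' @export
prob_readout <- function(y) {
  sin(y)^2
}

#' Construct parameters for one quantum layer
#'
#' A layer holds three matrices of identical shape `n_in x n_units`: real
#' connection weights `W`, reversal parameters `eps`, and phase thresholds
#' `theta`.  The learning rules update all three per connection; the forward
#' pass collapses `eps` and `theta` to per-unit scalars by the column mean.
#' All entries initialize from U(0, 1).
#'
#' @param n_in Number of input lines.
#' @param n_units Number of units in the layer.
#' @param w_scale Upper bound of the uniform weight initialization:
#'   `W ~ U(0, w_scale)`.  Reversal and threshold parameters always draw
#'   from U(0, 1).  Small weight scales start the network's pre-activations
#'   near the threshold phasor, giving a low initial conditioned response.
#' @return An object of class `"qlayer"`.
#' @export
qlayer <- function(n_in, n_units, w_scale = 1) {
  stopifnot(n_in >= 1, n_units >= 1, w_scale > 0)
  draw <- function(s = 1) matrix(stats::runif(n_in * n_units, 0, s),
                                 n_in, n_units)
  structure(list(W = draw(w_scale), eps = draw(), theta = draw()),
            class = "qlayer")
}

# Re-draw the full parameter columns of selected units from the init
# distribution.  Used by training loops to recover from a degenerate
# (zero-modulus) pre-activation.
reinit_units <- function(params, units) {
  n_in <- nrow(params$W)
  for (j in units) {
    params$W[, j]     <- stats::runif(n_in)
    params$eps[, j]   <- stats::runif(n_in)
    params$theta[, j] <- stats::runif(n_in)
  }
  params
}

#' Forward pass through one quantum layer
#'
#' For each unit `j` with per-unit scalars `eps_j`, `theta_j` (column means
#' of the parameter matrices):
#' \deqn{v_j = \sum_i W_{ij} e^{i \tilde p_i} - e^{i \theta_j}}
#' \deqn{y_j = (\pi/2) S(\epsilon_j) - \mathrm{Arg}(v_j)}
#' \deqn{a_j = \sin^2(y_j)}
#' Hidden and output layers share this computation; only the parameters
#' differ.
#'
#' @param params A `qlayer`.
#' @param input_angles Phase-angle vector of length `nrow(params$W)`.
#' @return List with complex pre-activations `v`, phases `y`, and readout
#'   activations `a` in \[0, 1\].
#' @export
layer_forward <- function(params, input_angles) {
  if (length(input_angles) != nrow(params$W)) {
    stop("input length ", length(input_angles), " does not match layer fan-in ",
         nrow(params$W), call. = FALSE)
  }
  ph <- phasor(input_angles)
  v <- as.vector(crossprod(params$W, ph)) - phasor(colMeans(params$theta))
  y <- (pi / 2) * logsigmoid(colMeans(params$eps)) - complex_phase(v)
  list(v = v, y = y, a = prob_readout(y))
}

#' Error half-sum and mean absolute error of a training run
#'
#' The literal statistic is the signed half-sum `0.5 * sum(e)`; because
#' positive and negative errors cancel there, the mean of `|e|` is reported
#' alongside as the usual diagnostic.
#'
#' @param errors Nonempty numeric vector of per-trial errors.
#' @return List with components `literal` and `mean_abs`.
#' @export
error_statistic <- function(errors) {
  if (length(errors) == 0L) stop("empty error vector", call. = FALSE)
  list(literal = 0.5 * sum(errors), mean_abs = mean(abs(errors)))
}
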