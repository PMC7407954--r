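# Cortical module: an adaptive single-output feedforward quantum network
# (ASLFFQNN).  The hidden layer learns by the instar rule; the single output
# unit learns by the Widrow-Hoff (LMS) rule against the US target.  Its
# output readout is the conditioned response CR in [0, 1].

#' Construct a cortical network state
#'
#' @param r Number of cue lines.
#' @param q Number of hidden qubits.
#' @param w_scale Weight-initialization scale passed to [qlayer()].
#' @return An object of class `"cortical_state"` with `layer1` (r x q),
#'   `layer2` (q x 1), and the last hidden activation / CR.
#' @export
cortical_state <- function(r, q, w_scale = 1) {
  stopifnot(r >= 1, q >= 1)
  structure(list(layer1 = qlayer(r, q, w_scale),
                 layer2 = qlayer(q, 1L, w_scale),
                 last_hidden = rep(NA_real_, q), last_cr = NA_real_),
            class = "cortical_state")
}

#' Cortical forward pass: cue to conditioned response
#'
#' @param state A `cortical_state`.
#' @param p Cue vector in \[0, 1\]^r.
#' @return The state with `last_hidden` (a_c1) and `last_cr` updated; the
#'   CR is the |1>-state probability of the output unit.
#' @export
cor_forward <- function(state, p) {
  if (length(p) != nrow(state$layer1$W)) {
    stop("cue length ", length(p), " does not match network input width ",
         nrow(state$layer1$W), call. = FALSE)
  }
  h <- with_layer_tag(layer_forward(state$layer1, encode_input(p)), "c1")
  o <- with_layer_tag(layer_forward(state$layer2, encode_input(h$a)), "c2")
  state$last_hidden <- h$a
  state$last_cr <- o$a[1L]
  state
}

#' Instar update of the cortical hidden layer
#'
#' Same rule as the hippocampal instar, applied to the cortical layer 1.
#'
#' @inheritParams instar_update
#' @param a_c1 Hidden activation from the same trial's forward pass.
#' @export
cor_instar_update <- function(state, p, a_c1, cfg) {
  state$layer1 <- instar_step(state$layer1, p, a_c1, cfg)
  state
}

#' Widrow-Hoff update of the cortical output layer
#'
#' `W_i <- W_i + mu * a_i * e` applied to the output unit's weight,
#' reversal and threshold columns, with `e` the trial's prediction error.
#'
#' @param state A `cortical_state`.
#' @param a_c1 Hidden activation vector from the trial.
#' @param error Scalar prediction error.
#' @param cfg A `learning_config`.
#' @return Updated state.
#' @export
widrow_hoff_update <- function(state, a_c1, error, cfg) {
  delta <- cfg$mu * a_c1 * error
  state$layer2$W <- state$layer2$W + delta
  state$layer2$eps <- state$layer2$eps + delta
  state$layer2$theta <- state$layer2$theta + delta
  if (cfg$clamp_eps) {
    state$layer2$eps <- pmin(pmax(state$layer2$eps, 0), 1)
  }
  state
}

#' One supervised cortical training trial
#'
#' Forward pass; target `d = 1` if the US is present, else 0; error
#' `e = cr - d` under the default literal convention (`e = d - cr` under
#' the flipped convention, a negative control); instar update of layer 1,
#' Widrow-Hoff update of layer 2.
#'
#' @param state A `cortical_state`.
#' @param p Cue vector.
#' @param us_present Logical: is the US paired with this cue?
#' @param cfg A `learning_config`.
#' @return List with the updated `state` and a `record` list holding
#'   `cr`, `target`, and `error`.
#' @export
cor_train_trial <- function(state, p, us_present, cfg) {
  state <- cor_forward(state, p)
  cr <- state$last_cr
  d <- as.numeric(isTRUE(us_present))
  e <- if (cfg$error_convention == "flipped") d - cr else cr - d
  state <- cor_instar_update(state, p, state$last_hidden, cfg)
  state <- widrow_hoff_update(state, state$last_hidden, e, cfg)
  list(state = state, record = list(cr = cr, target = d, error = e))
}
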