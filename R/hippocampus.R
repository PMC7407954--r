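# Hippocampal module: an autoencoder quantum neural network (AQNN).
# Layer 1 (cue -> hidden) learns by the instar rule, layer 2 (hidden ->
# reconstruction) by the outstar rule; both are unsupervised.  The hidden
# readout a_h1 is the internal representation forwarded to the cortex in
# intact systems.

#' Construct a hippocampal autoencoder state
#'
#' @param r Number of cue lines (input and reconstruction width).
#' @param q Number of hidden qubits.
#' @param w_scale Weight-initialization scale passed to [qlayer()].
#' @return An object of class `"hippocampal_state"` with `layer1` (r x q),
#'   `layer2` (q x r), and the last hidden/reconstruction activations.
#' @export
hippocampal_state <- function(r, q, w_scale = 1) {
  stopifnot(r >= 1, q >= 1)
  structure(list(layer1 = qlayer(r, q, w_scale),
                 layer2 = qlayer(q, r, w_scale),
                 last_hidden = rep(NA_real_, q),
                 last_recon = rep(NA_real_, r)),
            class = "hippocampal_state")
}

#' Hippocampal forward pass
#'
#' Encodes the cue, reads the hidden representation, re-encodes it, and
#' reads the reconstruction.  Activations are |1>-state probabilities, so
#' the hidden vector can be phase-encoded again with the same cue encoding.
#'
#' @param state A `hippocampal_state`.
#' @param p Cue vector in \[0, 1\]^r.
#' @return The state with `last_hidden` (a_h1) and `last_recon` (a_h2)
#'   updated.
#' @export
hip_forward <- function(state, p) {
  if (length(p) != nrow(state$layer1$W)) {
    stop("cue length ", length(p), " does not match network input width ",
         nrow(state$layer1$W), call. = FALSE)
  }
  h1 <- with_layer_tag(layer_forward(state$layer1, encode_input(p)), "h1")
  h2 <- with_layer_tag(layer_forward(state$layer2, encode_input(h1$a)), "h2")
  state$last_hidden <- h1$a
  state$last_recon <- h2$a
  state
}

# Re-signal a degenerate-preactivation error with the layer name attached so
# the training loop knows which parameter block to re-randomize.
with_layer_tag <- function(expr, layer) {
  withCallingHandlers(expr, chcq_degenerate = function(c) {
    c$layer <- layer
    stop(c)
  })
}

# Shared instar arithmetic: move each column of every parameter matrix
# toward the input pattern, gated by that unit's (contrast-sharpened)
# activation.
#   M_ij <- M_ij + mu * a_j^beta * (p_i - M_ij)
instar_step <- function(params, p, a, cfg) {
  g <- if (cfg$instar_contrast == 1) a else a^cfg$instar_contrast
  for (nm in c("W", "eps", "theta")) {
    m <- params[[nm]]
    params[[nm]] <- m + cfg$mu * sweep(p - m, 2L, g, "*")
  }
  if (cfg$clamp_eps) params$eps <- pmin(pmax(params$eps, 0), 1)
  params
}

# Shared outstar arithmetic: move each parameter toward the target pattern
# over the columns, gated by the source (row) activation.
#   M_ij <- M_ij + mu * (t_j - M_ij) * a_i
outstar_step <- function(params, a_src, target, cfg) {
  tgt <- matrix(target, nrow(params$W), ncol(params$W), byrow = TRUE)
  for (nm in c("W", "eps", "theta")) {
    m <- params[[nm]]
    params[[nm]] <- m + cfg$mu * (tgt - m) * a_src
  }
  if (cfg$clamp_eps) params$eps <- pmin(pmax(params$eps, 0), 1)
  params
}

#' Instar update of the hippocampal input layer
#'
#' Applies `W_ij <- W_ij + mu * a_j * (p_i - W_ij)` to the weight, reversal
#' and threshold matrices of layer 1, with `a` the hidden activation from
#' the same trial's forward pass.
#'
#' @param state A `hippocampal_state`.
#' @param p Cue vector.
#' @param a_h1 Hidden activation vector from the same trial.
#' @param cfg A `learning_config`.
#' @return Updated state.
#' @export
instar_update <- function(state, p, a_h1, cfg) {
  state$layer1 <- instar_step(state$layer1, p, a_h1, cfg)
  state
}

#' Outstar update of the hippocampal output layer
#'
#' Applies `W_ij <- W_ij + mu * (t_j - W_ij) * a_i` to layer 2, with source
#' activation `a_h1` gating each row.  In `"literal"` mode the drive `t` is
#' the network's own reconstruction `a_h2`; in `"input_target"` mode it is
#' the cue `p`, the classical outstar target for an autoencoder.
#'
#' @param state A `hippocampal_state`.
#' @param a_h1,a_h2 Hidden and reconstruction activations from the trial.
#' @param p Cue vector (used as the drive in `"input_target"` mode).
#' @param cfg A `learning_config`.
#' @return Updated state.
#' @export
outstar_update <- function(state, a_h1, a_h2, p, cfg) {
  target <- if (cfg$outstar_target_mode == "input_target") p else a_h2
  state$layer2 <- outstar_step(state$layer2, a_h1, target, cfg)
  state
}

#' One unsupervised hippocampal training trial
#'
#' Forward pass, instar update of layer 1, outstar update of layer 2.
#'
#' @param state A `hippocampal_state`.
#' @param p Cue vector.
#' @param cfg A `learning_config`.
#' @return List with the updated `state` and the reconstruction error
#'   `recon_error = mean(|a_h2 - p|)`.
#' @export
hip_train_trial <- function(state, p, cfg) {
  state <- hip_forward(state, p)
  a_h1 <- state$last_hidden
  a_h2 <- state$last_recon
  state <- instar_update(state, p, a_h1, cfg)
  state <- outstar_update(state, a_h1, a_h2, p, cfg)
  list(state = state, recon_error = mean(abs(a_h2 - p)))
}
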