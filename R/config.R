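# Configuration records.  Defaults are the shipped calibration: one global
# learning rate for all rules, six hidden qubits, and a moderate per-trial
# hippocampus-to-cortex blend (see calibrate_chcq()).

#' Learning configuration
#'
#' @param mu Learning rate shared by the instar, outstar and Widrow-Hoff
#'   rules; a small positive number in (0, 1].
#' @param outstar_target_mode `"literal"` drives the outstar rule with the
#'   autoencoder's own output activations; `"input_target"` drives it with
#'   the cue, the classical reconstruction target.
#' @param error_convention Widrow-Hoff error sign. `"literal"` (default)
#'   uses `e = cr - d`, the sign under which the conditioned response
#'   converges to the US target in this phase parameterization (a uniform
#'   increase of the output unit's weight, reversal and threshold
#'   parameters lowers the CR, so the nominal gradient direction is
#'   reversed relative to a linear LMS unit); `"flipped"` uses
#'   `e = d - cr` and is kept as a documented negative control under which
#'   the CR diverges from the target.
#' @param instar_contrast Competitive sharpening exponent for the instar
#'   gating: updates are gated by `a^instar_contrast` instead of the raw
#'   activation `a`.  1 is the plain instar rule; larger values
#'   concentrate learning on the most active units (soft winner-take-all,
#'   in the spirit of the competitive coding layer the instar rule
#'   classically pairs with), which preserves between-stimulus
#'   differentiation of the hidden representation.
#' @param clamp_eps If `TRUE`, reversal parameters are clamped to \[0, 1\]
#'   after every update.
#' @return An object of class `"learning_config"`.
#' @export
learning_config <- function(mu = 1,
                            outstar_target_mode = c("literal", "input_target"),
                            error_convention = c("literal", "flipped"),
                            instar_contrast = 3,
                            clamp_eps = FALSE) {
  stopifnot(is.numeric(mu), length(mu) == 1L, mu >= 0, mu <= 1,
            is.numeric(instar_contrast), instar_contrast >= 1)
  structure(list(mu = mu,
                 outstar_target_mode = match.arg(outstar_target_mode),
                 error_convention = match.arg(error_convention),
                 instar_contrast = instar_contrast,
                 clamp_eps = isTRUE(clamp_eps)),
            class = "learning_config")
}

#' Hippocampus-to-cortex coupling configuration
#'
#' The hippocampal internal representation reaches the cortex as an adaptive
#' parameter signal: cortical hidden-layer parameters are blended toward the
#' hippocampal hidden-layer parameters, once at build time with weight
#' `lambda_init` and after every trial with weight `lambda_trial`.
#'
#' @param lambda_init Blend weight at initialization, in \[0, 1\]; 1 copies
#'   the hippocampal hidden layer into the cortex exactly.
#' @param lambda_trial Per-trial blend weight, in \[0, 1\]; 0 decouples the
#'   two networks after initialization.
#' @param noise_sigma Standard deviation of zero-mean Gaussian noise added to
#'   the transferred parameters, modelling disrupted internal
#'   representations; 0 disables it.
#' @return An object of class `"coupling_config"`.
#' @export
coupling_config <- function(lambda_init = 1.0, lambda_trial = 0.5,
                            noise_sigma = 0) {
  stopifnot(lambda_init >= 0, lambda_init <= 1,
            lambda_trial >= 0, lambda_trial <= 1,
            noise_sigma >= 0)
  structure(list(lambda_init = lambda_init, lambda_trial = lambda_trial,
                 noise_sigma = noise_sigma),
            class = "coupling_config")
}

#' Steady-state criterion configuration
#'
#' Learning on an item ends when its conditioned response stays at the
#' target steady state -- at or above `hi` for reinforced items, at or below
#' `lo` for unreinforced ones -- for `consecutive` successive sweeps.
#'
#' @param hi Upper threshold for CR ~ 1 items (default 0.9).
#' @param lo Lower threshold for CR ~ 0 items (default 0.15).
#' @param consecutive Number of successive sweeps the threshold must hold.
#' @param max_trials Sweep budget before a phase is declared not reached.
#' @return An object of class `"criterion_config"`.
#' @export
criterion_config <- function(hi = 0.9, lo = 0.15, consecutive = 3,
                             max_trials = 500) {
  stopifnot(lo >= 0, hi <= 1, lo < hi, consecutive >= 1, max_trials >= 1)
  structure(list(hi = hi, lo = lo, consecutive = as.integer(consecutive),
                 max_trials = as.integer(max_trials)),
            class = "criterion_config")
}
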