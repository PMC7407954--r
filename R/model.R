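# The assembled cortico-hippocampal model.  An intact system couples the
# two networks through an adaptive parameter signal: the cortical hidden
# layer is blended toward the hippocampal hidden layer at build time
# (lambda_init) and after every trial (lambda_trial).  Lesioning removes
# that link; the hippocampal state is retained but never read again.

#' Build a cortico-hippocampal qubit-network model
#'
#' Initializes both networks from U(0, 1) draws.  The cortical and
#' hippocampal parameter draws come from independent seed streams derived
#' from `seed`, so a lesioned system's behaviour depends only on the
#' cortical stream.  In an intact system the cortical hidden layer is
#' blended toward the hippocampal hidden layer with weight
#' `coupling$lambda_init`; a lesioned system keeps its purely random draw.
#'
#' @param r Cue width (default 5: two stimulus amplitudes plus three
#'   one-hot context slots).
#' @param q Number of hidden qubits in each network.
#' @param lesioned Logical: build without the hippocampus-to-cortex link?
#' @param learning A [learning_config()].
#' @param coupling A [coupling_config()].
#' @param w_init Weight-initialization scale (`W ~ U(0, w_init)` in every
#'   layer); reversal and threshold parameters draw from U(0, 1).
#' @param hip_us If `TRUE` (default), the hippocampal autoencoder receives
#'   the US flag as an additional input line and learns to reconstruct it
#'   alongside the cue, so its internal representation encodes the
#'   stimulus-reinforcer contingency.  The cortex never sees this line;
#'   the adaptive transfer maps only the shared cue rows.  With `FALSE`
#'   the hippocampus autoencodes the cue alone.
#' @param seed Integer seed for the cortical parameter stream and the
#'   trial-time noise stream.
#' @param hip_seed Integer seed for the hippocampal parameter stream;
#'   defaults to a fixed offset from `seed`.
#' @return An object of class `"chcq"`.
#' @examples
#' m <- chcq(seed = 1)
#' m
#' @export
chcq <- function(r = 5L, q = 6L, lesioned = FALSE,
                 learning = learning_config(),
                 coupling = coupling_config(), w_init = 0.5, hip_us = TRUE,
                 seed = 1L, hip_seed = seed + 1000003L) {
  stopifnot(r >= 1, q >= 1)
  stopifnot(inherits(learning, "learning_config"),
            inherits(coupling, "coupling_config"))
  set.seed(as.integer(seed))
  cortex <- cortical_state(r, q, w_init)
  set.seed(as.integer(hip_seed))
  hippocampus <- hippocampal_state(r + as.integer(isTRUE(hip_us)), q, w_init)
  set.seed(as.integer(seed) + 2000003L)
  rngstate <- .Random.seed
  model <- structure(
    list(hippocampus = hippocampus, cortex = cortex,
         coupling = coupling, learning = learning,
         lesioned = isTRUE(lesioned), w_init = w_init,
         hip_us = isTRUE(hip_us),
         r = as.integer(r), q = as.integer(q),
         seed = as.integer(seed), hip_seed = as.integer(hip_seed),
         n_trials = 0L, n_reinits = 0L, rngstate = rngstate),
    class = "chcq")
  if (!model$lesioned && coupling$lambda_init > 0) {
    model$cortex$layer1 <- blend_qlayer(model$cortex$layer1,
                                        model$hippocampus$layer1,
                                        coupling$lambda_init)
  }
  model
}

# Elementwise blend of two parameter blocks: (1 - lambda) a + lambda b.
# When b has extra input rows (the hippocampal US line), only the rows
# shared with a take part in the mapping.
blend_qlayer <- function(a, b, lambda, noise_sigma = 0) {
  rows <- seq_len(nrow(a$W))
  for (nm in c("W", "eps", "theta")) {
    mixed <- (1 - lambda) * a[[nm]] + lambda * b[[nm]][rows, , drop = FALSE]
    if (noise_sigma > 0) {
      mixed <- mixed + matrix(stats::rnorm(length(mixed), 0, noise_sigma),
                              nrow(mixed), ncol(mixed))
    }
    a[[nm]] <- mixed
  }
  a
}

# Run `expr` under the model's private RNG stream and save the advanced
# state back, so trial-time noise is reproducible and independent of the
# caller's RNG.
with_model_rng <- function(model, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", model$rngstate, envir = globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  value <- force(expr)
  state <- get(".Random.seed", envir = globalenv())
  list(value = value, model = { model$rngstate <- state; model })
}

#' Transfer the hippocampal parameter signal to the cortex
#'
#' Blends the cortical hidden-layer parameters toward the hippocampal
#' hidden-layer parameters with weight `lambda_trial`, optionally adding
#' zero-mean Gaussian noise (`noise_sigma`) to model disrupted internal
#' representations.  A no-op (with a warning) on lesioned models.
#'
#' @param model A `chcq` model.
#' @return The updated model.
#' @export
adaptive_transfer <- function(model) {
  if (model$lesioned) {
    warning("adaptive_transfer() on a lesioned model is a no-op")
    return(model)
  }
  lam <- model$coupling$lambda_trial
  sig <- model$coupling$noise_sigma
  if (lam == 0 && sig == 0) return(model)
  if (sig > 0) {
    out <- with_model_rng(model, blend_qlayer(model$cortex$layer1,
                                              model$hippocampus$layer1,
                                              lam, sig))
    model <- out$model
    model$cortex$layer1 <- out$value
  } else {
    model$cortex$layer1 <- blend_qlayer(model$cortex$layer1,
                                        model$hippocampus$layer1, lam)
  }
  model
}

#' Lesion the hippocampus-to-cortex link
#'
#' Marks the model lesioned: the hippocampal state is kept but no longer
#' trained or read.  Idempotent.
#'
#' @param model A `chcq` model.
#' @return The lesioned model.
#' @export
lesion <- function(model) {
  model$lesioned <- TRUE
  model
}

#' Run one conditioning trial
#'
#' The fixed within-trial order is: (1) one unsupervised hippocampal
#' training trial (intact systems only); (2) adaptive transfer of the
#' hippocampal parameters to the cortex (intact only); (3) one supervised
#' cortical training trial against the US target.  A degenerate
#' pre-activation (a zero-modulus complex sum, which leaves the phase
#' undefined) causes the offending unit's parameters to be re-drawn from
#' the init distribution and the trial to be retried.
#'
#' @param model A `chcq` model.
#' @param p Cue vector in \[0, 1\]^r.
#' @param us_present Logical US pairing flag.
#' @return List with the scalar `cr`, the updated `model`, and the trial
#'   `record` (cr, target, error).
#' @export
model_trial <- function(model, p, us_present) {
  for (attempt in seq_len(25L)) {
    result <- tryCatch({
      m <- model
      if (!m$lesioned) {
        hp <- if (m$hip_us) c(p, as.numeric(isTRUE(us_present))) else p
        ht <- hip_train_trial(m$hippocampus, hp, m$learning)
        m$hippocampus <- ht$state
        m <- adaptive_transfer(m)
      }
      ct <- cor_train_trial(m$cortex, p, us_present, m$learning)
      m$cortex <- ct$state
      m$n_trials <- m$n_trials + 1L
      list(cr = ct$record$cr, model = m, record = ct$record)
    }, chcq_degenerate = function(c) c)
    if (!inherits(result, "chcq_degenerate")) return(result)
    model <- recover_degenerate(model, result)
  }
  stop("degenerate pre-activation persisted after 25 re-initializations",
       call. = FALSE)
}

# Re-draw the parameters of the units whose pre-activation collapsed to
# zero, in the layer tagged on the condition object.
recover_degenerate <- function(model, cond) {
  layer <- if (is.null(cond$layer)) "c1" else cond$layer
  units <- if (is.null(cond$units)) 1L else cond$units
  out <- with_model_rng(model, switch(layer,
    h1 = reinit_units(model$hippocampus$layer1, units),
    h2 = reinit_units(model$hippocampus$layer2, units),
    c1 = reinit_units(model$cortex$layer1, units),
    c2 = reinit_units(model$cortex$layer2, units)))
  model <- out$model
  model$n_reinits <- model$n_reinits + 1L
  switch(layer,
         h1 = model$hippocampus$layer1 <- out$value,
         h2 = model$hippocampus$layer2 <- out$value,
         c1 = model$cortex$layer1 <- out$value,
         c2 = model$cortex$layer2 <- out$value)
  model
}

#' @export
print.chcq <- function(x, ...) {
  cat("Cortico-hippocampal qubit-network model\n")
  cat(sprintf("  system:   %s\n", if (x$lesioned) "lesioned" else "intact"))
  cat(sprintf("  cue width R = %d, hidden qubits Q = %d\n", x$r, x$q))
  cat(sprintf("  learning: mu = %g (%s error, outstar %s)\n",
              x$learning$mu, x$learning$error_convention,
              x$learning$outstar_target_mode))
  cat(sprintf("  coupling: lambda_init = %g, lambda_trial = %g, sigma = %g\n",
              x$coupling$lambda_init, x$coupling$lambda_trial,
              x$coupling$noise_sigma))
  cat(sprintf("  trials run: %d", x$n_trials))
  if (x$n_reinits > 0) cat(sprintf("  (unit re-inits: %d)", x$n_reinits))
  cat("\n")
  invisible(x)
}

#' @export
summary.chcq <- function(object, ...) {
  out <- list(
    system = if (object$lesioned) "lesioned" else "intact",
    r = object$r, q = object$q, n_trials = object$n_trials,
    last_cr = object$cortex$last_cr,
    last_hidden = object$cortex$last_hidden,
    recon = object$hippocampus$last_recon)
  class(out) <- "summary.chcq"
  out
}

#' @export
print.summary.chcq <- function(x, ...) {
  cat(sprintf("%s system (R = %d, Q = %d), %d trials run\n",
              x$system, x$r, x$q, x$n_trials))
  cat(sprintf("  last CR: %s\n", format(x$last_cr, digits = 4)))
  if (!all(is.na(x$recon))) {
    cat("  last hippocampal reconstruction:",
        paste(format(x$recon, digits = 3), collapse = " "), "\n")
  }
  invisible(x)
}
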