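# Classical comparison network: a generic one-hidden-layer sigmoid
# feedforward net trained online by backpropagation of the squared error
# (the delta rule at the output).  Serves as the non-quantum control the
# lesioned system is compared against.

#' Run a paradigm on a generic feedforward baseline network
#'
#' Trains a standard multilayer perceptron (one logistic hidden layer of
#' `q` units, logistic output) on the same cues, sweep structure, and
#' steady-state criterion as the qubit-network model, with online
#' gradient updates at rate `mu`.
#'
#' @param paradigm A [make_paradigm()] object or paradigm name.
#' @param q Hidden units (default 8).
#' @param mu Learning rate (default 1, a typical online rate for logistic
#'   units on \[0, 1\] targets).
#' @param criterion A [criterion_config()].
#' @param seed RNG seed for the N(0, 0.5) weight initialization.
#' @return List with per-phase `trials`, `reached`, and the final weights.
#' @export
baseline_feedforward <- function(paradigm, q = 8, mu = 1,
                                 criterion = criterion_config(),
                                 seed = 1) {
  if (is.character(paradigm)) paradigm <- make_paradigm(paradigm)
  set.seed(as.integer(seed))
  r <- 5L
  net <- list(W1 = matrix(stats::rnorm(r * q, 0, 0.5), r, q),
              b1 = stats::rnorm(q, 0, 0.5),
              W2 = matrix(stats::rnorm(q, 0, 0.5), q, 1),
              b2 = stats::rnorm(1, 0, 0.5))
  fwd <- function(net, p) {
    h <- stats::plogis(as.vector(crossprod(net$W1, p)) + net$b1)
    o <- stats::plogis(sum(net$W2 * h) + net$b2)
    list(h = h, o = o)
  }
  step <- function(net, p, d) {
    f <- fwd(net, p)
    delta_o <- (d - f$o) * f$o * (1 - f$o)
    delta_h <- as.vector(net$W2) * delta_o * f$h * (1 - f$h)
    net$W2 <- net$W2 + mu * delta_o * f$h
    net$b2 <- net$b2 + mu * delta_o
    net$W1 <- net$W1 + mu * outer(p, delta_h)
    net$b1 <- net$b1 + mu * delta_h
    list(net = net, cr = f$o)
  }
  trials <- integer(0)
  reached <- logical(0)
  for (ph in paradigm$phases) {
    cues <- lapply(ph$items, encode_cue)
    targets <- vapply(ph$items, function(it) as.numeric(it$us), numeric(1))
    histories <- rep(list(numeric(0)), length(cues))
    limit <- if (ph$mode == "fixed") ph$fixed_length else criterion$max_trials
    sweep_i <- 0L
    repeat {
      sweep_i <- sweep_i + 1L
      for (it in seq_along(cues)) {
        s <- step(net, cues[[it]], targets[it])
        net <- s$net
        histories[[it]] <- c(histories[[it]], s$cr)
      }
      if (ph$mode == "fixed") {
        if (sweep_i >= limit) break
      } else {
        ssi <- vapply(seq_along(cues), function(it)
          steady_state_index(histories[[it]], targets[it], criterion),
          integer(1))
        if (all(!is.na(ssi)) || sweep_i >= limit) break
      }
    }
    if (ph$mode == "fixed") {
      trials <- c(trials, ph$fixed_length)
      reached <- c(reached, TRUE)
    } else {
      ssi <- vapply(seq_along(cues), function(it)
        steady_state_index(histories[[it]], targets[it], criterion),
        integer(1))
      ok <- all(!is.na(ssi))
      trials <- c(trials, if (ok) max(ssi) else NA_integer_)
      reached <- c(reached, ok)
    }
  }
  names(trials) <- paste0("phase", seq_along(trials))
  list(trials = trials, reached = reached, net = net)
}
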