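# Conditioning paradigms: cue encoding, the task catalogue, the sustained
# steady-state criterion, and trials-to-criterion measurement.
#
# A cue presents up to two conditioned stimuli A and B (amplitudes in
# [0, 1]) inside one of three contexts X, Y, Z; "+" marks pairing with the
# unconditioned stimulus.  The cue vector has the fixed layout
# [amp_A, amp_B, ctx_X, ctx_Y, ctx_Z], so R = 5 throughout.

CONTEXTS <- c("X", "Y", "Z")

#' Specify a single conditioning cue
#'
#' @param amp_A,amp_B Stimulus amplitudes in \[0, 1\].
#' @param context One of `"X"`, `"Y"`, `"Z"`.
#' @param us Logical: paired with the unconditioned stimulus?
#' @param label Display label; generated from the fields if omitted.
#' @return An object of class `"cue_spec"`.
#' @examples
#' cue_spec(1, 0, "X", us = TRUE)   # AX+
#' @export
cue_spec <- function(amp_A = 0, amp_B = 0, context = "X", us = FALSE,
                     label = NULL) {
  stopifnot(amp_A >= 0, amp_A <= 1, amp_B >= 0, amp_B <= 1)
  context <- match.arg(context, CONTEXTS)
  if (is.null(label)) {
    stim <- paste0(if (amp_A > 0) if (amp_A == 1) "A" else paste0("A", amp_A),
                   if (amp_B > 0) if (amp_B == 1) "B" else paste0("B", amp_B))
    label <- paste0(stim, context, if (us) "+" else "-")
  }
  structure(list(amp_A = amp_A, amp_B = amp_B, context = context,
                 us = isTRUE(us), label = label),
            class = "cue_spec")
}

#' Encode a cue specification as the model input vector
#'
#' @param spec A [cue_spec()].
#' @return Numeric vector `[amp_A, amp_B, 1{X}, 1{Y}, 1{Z}]` in \[0, 1\]^5.
#' @examples
#' encode_cue(cue_spec(1, 0, "X", us = TRUE))   # c(1, 0, 1, 0, 0)
#' @export
encode_cue <- function(spec) {
  stopifnot(inherits(spec, "cue_spec"))
  c(spec$amp_A, spec$amp_B, as.numeric(CONTEXTS == spec$context))
}

#' Move a cue to a different context
#'
#' @param spec A [cue_spec()].
#' @param new_context A context different from the cue's current one.
#' @return The cue with its context replaced (amplitudes and US unchanged).
#' @export
shift_context <- function(spec, new_context) {
  new_context <- match.arg(new_context, CONTEXTS)
  if (new_context == spec$context) {
    stop("new context equals the current context ('", spec$context, "')",
         call. = FALSE)
  }
  cue_spec(spec$amp_A, spec$amp_B, new_context, spec$us)
}

# A training phase: an ordered item list run either to the steady-state
# criterion or for a fixed number of sweeps.
phase <- function(items, mode = c("to_criterion", "fixed"),
                  fixed_length = NULL) {
  mode <- match.arg(mode)
  if (inherits(items, "cue_spec")) items <- list(items)
  stopifnot(length(items) >= 1)
  if (mode == "fixed") {
    stopifnot(is.numeric(fixed_length), fixed_length >= 1)
  } else {
    stopifnot(is.null(fixed_length))
  }
  structure(list(items = items, mode = mode,
                 fixed_length = if (is.null(fixed_length)) NULL
                                else as.integer(fixed_length)),
            class = "chcq_phase")
}

#' The conditioning task catalogue
#'
#' Builds the phase structure of a named paradigm.  Pre-exposure phases
#' whose length is part of the protocol (rather than learned) are fixed:
#' 50 sweeps for latent-inhibition and sensory-preconditioning
#' pre-exposure (and the final sensory-preconditioning extinction probe),
#' 20 sweeps for the compound phase of overshadowing and compound
#' preconditioning.  All other phases run to the steady-state criterion.
#'
#' Available paradigms: `a_plus` (AX+), `a_minus` (AX-),
#' `stimulus_discrimination` (AX+, BX-), `discrimination_reversal`,
#' `blocking`, `overshadowing`, `easy_hard_transfer`, `latent_inhibition`,
#' `sensory_preconditioning`, `compound_preconditioning`, `context_shift`
#' (AX+ then AY+), `li_context_shift` (AX- then AY+),
#' `feedforward_comparison` (AX- pre-exposure then AX+), plus the extended
#' variants `extended_blocking`, `extended_overshadowing`,
#' `extended_context` (the relevant phase lengthened by `extend_factor`)
#' and `disrupted_discrimination` (discrimination under representation
#' noise; the paradigm carries a `noise_sigma` attribute).
#'
#' @param name Paradigm name (see above).
#' @param extend_factor Multiplier applied to the lengthened phase of the
#'   extended variants (default 3).
#' @return An object of class `"paradigm"`: a name plus an ordered list of
#'   phases.
#' @export
make_paradigm <- function(name, extend_factor = 3) {
  AXp <- cue_spec(1, 0, "X", us = TRUE)
  AXm <- cue_spec(1, 0, "X", us = FALSE)
  BXp <- cue_spec(0, 1, "X", us = TRUE)
  BXm <- cue_spec(0, 1, "X", us = FALSE)
  ABXp <- cue_spec(1, 1, "X", us = TRUE)
  ABXm <- cue_spec(1, 1, "X", us = FALSE)
  AYp <- cue_spec(1, 0, "Y", us = TRUE)
  tc <- function(...) phase(list(...))
  fx <- function(n, ...) phase(list(...), "fixed", n)
  phases <- switch(
    name,
    a_plus = list(tc(AXp)),
    a_minus = list(tc(AXm)),
    stimulus_discrimination = list(tc(AXp, BXm)),
    discrimination_reversal = list(tc(AXp, BXm), tc(AXm, BXp)),
    blocking = list(tc(AXp), tc(ABXp), tc(BXm)),
    overshadowing = list(fx(20, ABXp), tc(AXp, BXp)),
    easy_hard_transfer = list(
      tc(cue_spec(0.9, 0, "X", us = TRUE), cue_spec(0.1, 0, "X", us = FALSE)),
      tc(cue_spec(0.6, 0, "X", us = TRUE), cue_spec(0.4, 0, "X", us = FALSE))),
    latent_inhibition = list(fx(50, AXm), tc(AXp)),
    sensory_preconditioning = list(fx(50, ABXm), tc(AXp), fx(50, BXm)),
    compound_preconditioning = list(fx(20, ABXm), tc(AXp, BXm)),
    context_shift = list(tc(AXp), tc(AYp)),
    li_context_shift = list(fx(50, AXm), tc(AYp)),
    feedforward_comparison = list(fx(50, AXm), tc(AXp)),
    extended_blocking = list(tc(AXp), fx(20 * extend_factor, ABXp), tc(BXm)),
    extended_overshadowing = list(fx(20 * extend_factor, ABXp), tc(AXp, BXp)),
    extended_context = list(fx(50 * extend_factor, AXp), tc(AYp)),
    disrupted_discrimination = list(tc(AXp, BXm)),
    stop("unknown paradigm '", name, "'; valid names: ",
         paste(paradigm_names(), collapse = ", "), call. = FALSE))
  out <- structure(list(name = name, phases = phases), class = "paradigm")
  if (name == "disrupted_discrimination") attr(out, "noise_sigma") <- 0.1
  out
}

#' Names of all available paradigms
#' @return Character vector accepted by [make_paradigm()].
#' @export
paradigm_names <- function() {
  c("a_plus", "a_minus", "stimulus_discrimination",
    "discrimination_reversal", "blocking", "overshadowing",
    "easy_hard_transfer", "latent_inhibition", "sensory_preconditioning",
    "compound_preconditioning", "context_shift", "li_context_shift",
    "feedforward_comparison", "extended_blocking",
    "extended_overshadowing", "extended_context",
    "disrupted_discrimination")
}

#' @export
print.paradigm <- function(x, ...) {
  cat("Paradigm:", x$name, "\n")
  for (k in seq_along(x$phases)) {
    ph <- x$phases[[k]]
    lab <- vapply(ph$items, function(it) it$label, character(1))
    mode <- if (ph$mode == "fixed") paste0("fixed ", ph$fixed_length)
            else "to criterion"
    cat(sprintf("  phase %d: <%s>  [%s]\n", k,
                paste(lab, collapse = ", "), mode))
  }
  invisible(x)
}

#' First trial of a sustained steady-state run
#'
#' Scans a CR history for the first trial opening `consecutive` successive
#' trials with `cr >= hi` (target 1) or `cr <= lo` (target 0).
#'
#' @param cr_history Numeric vector of per-sweep CR values.
#' @param target 0 or 1, the desired steady state.
#' @param criterion A [criterion_config()].
#' @return The 1-based index, or `NA_integer_` if the criterion is never
#'   sustained.
#' @examples
#' steady_state_index(c(0.2, 0.5, 0.91, 0.95, 0.96), 1, criterion_config())
#' @export
steady_state_index <- function(cr_history, target, criterion) {
  stopifnot(length(cr_history) >= 1, target %in% c(0, 1))
  ok <- if (target == 1) cr_history >= criterion$hi
        else cr_history <= criterion$lo
  k <- criterion$consecutive
  if (length(ok) < k) return(NA_integer_)
  runs <- vapply(seq_len(length(ok) - k + 1L),
                 function(i) all(ok[i:(i + k - 1L)]), logical(1))
  idx <- which(runs)
  if (length(idx)) idx[1L] else NA_integer_
}

#' Run one training phase
#'
#' One trial is one sweep over the phase's items in listed order.  In
#' to-criterion mode the phase stops once every item's CR history sustains
#' its own criterion (high for reinforced items, low for unreinforced) and
#' reports the largest per-item steady-state index; in fixed mode it runs
#' exactly `fixed_length` sweeps.  Exhausting `max_trials` reports
#' `NA` trials with `reached = FALSE` (not an error).
#'
#' @param model A [chcq()] model.
#' @param ph A phase (one element of a paradigm's `phases`).
#' @param criterion A [criterion_config()].
#' @param phase_index Phase number recorded in the log.
#' @return List with `trials`, `reached`, a `log` data frame (one row per
#'   item presentation: phase, trial, item, cr, target), and the updated
#'   `model`.
#' @export
run_phase <- function(model, ph, criterion = criterion_config(),
                      phase_index = 1L) {
  n_items <- length(ph$items)
  cues <- lapply(ph$items, encode_cue)
  targets <- vapply(ph$items, function(it) as.numeric(it$us), numeric(1))
  labels <- vapply(ph$items, function(it) it$label, character(1))
  histories <- vector("list", n_items)
  limit <- if (ph$mode == "fixed") ph$fixed_length else criterion$max_trials
  sweep_i <- 0L
  repeat {
    sweep_i <- sweep_i + 1L
    for (it in seq_len(n_items)) {
      res <- model_trial(model, cues[[it]], targets[it] == 1)
      model <- res$model
      histories[[it]] <- c(histories[[it]], res$cr)
    }
    if (ph$mode == "fixed") {
      if (sweep_i >= limit) break
    } else {
      ssi <- vapply(seq_len(n_items), function(it)
        steady_state_index(histories[[it]], targets[it], criterion),
        integer(1))
      if (all(!is.na(ssi))) break
      if (sweep_i >= limit) break
    }
  }
  if (ph$mode == "fixed") {
    trials <- ph$fixed_length
    reached <- TRUE
  } else {
    ssi <- vapply(seq_len(n_items), function(it)
      steady_state_index(histories[[it]], targets[it], criterion),
      integer(1))
    reached <- all(!is.na(ssi))
    trials <- if (reached) max(ssi) else NA_integer_
  }
  log <- data.frame(
    phase = phase_index,
    trial = rep(seq_len(sweep_i), each = n_items),
    item = rep(labels, times = sweep_i),
    cr = unlist(lapply(seq_len(sweep_i), function(s)
      vapply(histories, `[[`, numeric(1), s))),
    target = rep(targets, times = sweep_i))
  list(trials = trials, reached = reached, log = log, model = model)
}

#' Run a full multi-phase paradigm
#'
#' Phases run in order on the same continuously learning model.
#'
#' @param model A [chcq()] model.
#' @param paradigm A [make_paradigm()] object or paradigm name.
#' @param criterion A [criterion_config()].
#' @return List with `trials` (named per-phase vector; `NA` where the
#'   criterion was not reached), `reached` (logical per phase), the
#'   combined `log` data frame, and the final `model`.
#' @export
run_paradigm <- function(model, paradigm, criterion = criterion_config()) {
  if (is.character(paradigm)) paradigm <- make_paradigm(paradigm)
  stopifnot(inherits(paradigm, "paradigm"))
  trials <- integer(0)
  reached <- logical(0)
  logs <- list()
  for (k in seq_along(paradigm$phases)) {
    res <- run_phase(model, paradigm$phases[[k]], criterion, phase_index = k)
    model <- res$model
    trials <- c(trials, res$trials)
    reached <- c(reached, res$reached)
    logs[[k]] <- res$log
  }
  names(trials) <- paste0("phase", seq_along(trials))
  list(trials = trials, reached = reached,
       log = do.call(rbind, logs), model = model)
}
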