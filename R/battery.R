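# Battery runner and calibration: repeats each paradigm over many seeded
# models, aggregates per-phase trials-to-criterion across seeds, and
# compares the medians with published reference counts.

#' Battery configuration
#'
#' @param tasks Character vector of paradigm names ([paradigm_names()]).
#' @param systems Subset of `c("intact", "lesioned")`.
#' @param n_seeds Number of independently seeded models per cell.
#' @param base_seed Seed of the first model; model `k` uses
#'   `base_seed + k - 1`.
#' @param aggregation `"median"` (default) or `"mean"` across seeds.
#' @param learning,coupling,criterion Component configurations.
#' @param q Hidden qubits per network (default 6, the calibrated value).
#' @param out_dir Directory for `summary.csv` and per-run trace CSVs;
#'   `NULL` disables writing.
#' @return An object of class `"battery_config"`.
#' @export
battery_config <- function(tasks = paradigm_names()[1:13],
                           systems = c("intact", "lesioned"),
                           n_seeds = 25, base_seed = 1,
                           aggregation = c("median", "mean"),
                           learning = learning_config(),
                           coupling = coupling_config(),
                           criterion = criterion_config(),
                           q = 6, out_dir = NULL) {
  stopifnot(length(tasks) >= 1, n_seeds >= 1)
  systems <- match.arg(systems, several.ok = TRUE)
  structure(list(tasks = tasks, systems = systems,
                 n_seeds = as.integer(n_seeds),
                 base_seed = as.integer(base_seed),
                 aggregation = match.arg(aggregation),
                 learning = learning, coupling = coupling,
                 criterion = criterion, q = as.integer(q),
                 out_dir = out_dir),
            class = "battery_config")
}

# One (task, system, seed) cell: fresh model, full paradigm.
run_battery_cell <- function(task, system, seed, config) {
  paradigm <- make_paradigm(task)
  coupling <- config$coupling
  sigma <- attr(paradigm, "noise_sigma")
  if (!is.null(sigma)) {
    coupling$noise_sigma <- max(coupling$noise_sigma, sigma)
  }
  model <- chcq(r = 5L, q = config$q, lesioned = (system == "lesioned"),
                learning = config$learning, coupling = coupling,
                seed = seed)
  run_paradigm(model, paradigm, config$criterion)
}

#' Run the conditioning task battery
#'
#' For every requested (task, system) pair, builds `n_seeds` fresh models,
#' runs the paradigm on each, and aggregates the per-phase
#' trials-to-criterion across seeds.  Runs that never reach criterion are
#' counted in `n_not_reached` and enter the aggregate at the `max_trials`
#' budget (never dropped silently).
#'
#' @param config A [battery_config()].
#' @return A data frame of class `"battery_result"` with columns `task`,
#'   `system`, `phase`, `trials_median` (or mean), `trials_iqr`,
#'   `n_seeds`, `n_not_reached`.  If `config$out_dir` is set, writes
#'   `summary.csv` and one `trace_<task>_<system>_<seed>.csv` per run.
#' @export
run_battery <- function(config = battery_config()) {
  agg <- if (config$aggregation == "median") stats::median else mean
  rows <- list()
  for (task in config$tasks) {
    for (system in config$systems) {
      seeds <- config$base_seed + seq_len(config$n_seeds) - 1L
      runs <- lapply(seeds, function(s)
        run_battery_cell(task, system, s, config))
      if (!is.null(config$out_dir)) {
        dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
        for (k in seq_along(runs)) {
          log <- runs[[k]]$log
          log <- data.frame(task = task, system = system,
                            seed = seeds[k], log)
          utils::write.csv(log, file.path(config$out_dir,
            sprintf("trace_%s_%s_%d.csv", task, system, seeds[k])),
            row.names = FALSE)
        }
      }
      n_phases <- length(runs[[1]]$trials)
      for (ph in seq_len(n_phases)) {
        tr <- vapply(runs, function(r) r$trials[ph], numeric(1))
        nr <- sum(is.na(tr))
        tr[is.na(tr)] <- config$criterion$max_trials
        rows[[length(rows) + 1L]] <- data.frame(
          task = task, system = system, phase = ph,
          trials_median = agg(tr),
          trials_iqr = stats::IQR(tr),
          n_seeds = config$n_seeds, n_not_reached = nr)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("battery_result", "data.frame")
  if (!is.null(config$out_dir)) {
    utils::write.csv(out, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
    writeLines(yaml::as.yaml(config_as_list(config)),
               file.path(config$out_dir, "config.yaml"))
  }
  out
}

config_as_list <- function(config) {
  list(tasks = config$tasks, systems = config$systems,
       n_seeds = config$n_seeds, base_seed = config$base_seed,
       aggregation = config$aggregation, q = config$q,
       learning = unclass(config$learning),
       coupling = unclass(config$coupling),
       criterion = unclass(config$criterion))
}

#' Build a battery configuration from a YAML file
#'
#' The file may contain top-level keys `battery` (tasks, systems, n_seeds,
#' base_seed, aggregation, q, out_dir), `learning`, `coupling`, and
#' `criterion`, each a mapping of the corresponding constructor's
#' arguments.  Missing keys fall back to the shipped defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return A [battery_config()].
#' @export
read_battery_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw$battery %||% list()
  if (!is.null(raw$learning)) {
    args$learning <- do.call(learning_config, raw$learning)
  }
  if (!is.null(raw$coupling)) {
    args$coupling <- do.call(coupling_config, raw$coupling)
  }
  if (!is.null(raw$criterion)) {
    args$criterion <- do.call(criterion_config, raw$criterion)
  }
  do.call(battery_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Published reference trial counts
#'
#' The trials-to-criterion counts reported for this class of
#' cortico-hippocampal model on the standard task battery, used as the
#' calibration reference.  Fixed-length pre-exposure phases are part of
#' the protocol and appear with their protocol lengths.
#'
#' @return Data frame with columns `task`, `system`, `phase`, `trials`.
#' @export
reference_counts <- function() {
  df <- read.csv(text = "task,system,phase,trials
a_plus,intact,1,23
a_plus,lesioned,1,18
a_minus,intact,1,2
a_minus,lesioned,1,2
stimulus_discrimination,intact,1,24
stimulus_discrimination,lesioned,1,17
discrimination_reversal,intact,1,24
discrimination_reversal,intact,2,22
discrimination_reversal,lesioned,1,17
discrimination_reversal,lesioned,2,32
blocking,intact,1,23
blocking,intact,2,24
blocking,intact,3,12
blocking,lesioned,1,18
blocking,lesioned,2,17
blocking,lesioned,3,3
overshadowing,intact,1,20
overshadowing,intact,2,25
overshadowing,lesioned,1,20
overshadowing,lesioned,2,22
easy_hard_transfer,intact,1,27
easy_hard_transfer,intact,2,34
easy_hard_transfer,lesioned,1,19
easy_hard_transfer,lesioned,2,20
latent_inhibition,intact,1,50
latent_inhibition,intact,2,31
latent_inhibition,lesioned,1,50
latent_inhibition,lesioned,2,18
sensory_preconditioning,intact,1,50
sensory_preconditioning,intact,2,31
sensory_preconditioning,intact,3,50
compound_preconditioning,intact,1,20
compound_preconditioning,intact,2,32
context_shift,intact,1,24
context_shift,intact,2,1
context_shift,lesioned,1,17
context_shift,lesioned,2,1
li_context_shift,intact,1,50
li_context_shift,intact,2,1
feedforward_comparison,lesioned,1,50
feedforward_comparison,lesioned,2,21
", stringsAsFactors = FALSE)
  df
}

#' Calibrate the default configuration against the reference counts
#'
#' Grid search over candidate configurations: each candidate is scored by
#' the summed relative deviation of its cross-seed median
#' trials-to-criterion from [reference_counts()], over the to-criterion
#' phases of the requested tasks.  Not-reached runs enter at the
#' `max_trials` budget, so chronically non-converging candidates score
#' badly rather than erroring.
#'
#' @param grid Data frame of candidates; recognised columns `mu`, `q`,
#'   `lambda_init`, `lambda_trial`, `hi`, `lo`, `consecutive` (missing
#'   columns take the shipped defaults).
#' @param tasks Paradigms scored (default: a fast informative subset).
#' @param n_seeds Seeds per cell during scoring.
#' @param reference Reference data frame (defaults to
#'   [reference_counts()]).
#' @return List with `best` (the winning candidate row, as a list of
#'   constructor-ready configs), and `scores` (the grid with a `score`
#'   column appended).
#' @export
calibrate_chcq <- function(grid,
                           tasks = c("a_plus", "a_minus",
                                     "stimulus_discrimination",
                                     "latent_inhibition", "blocking"),
                           n_seeds = 11,
                           reference = reference_counts()) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  col <- function(nm, default) {
    if (nm %in% names(grid)) grid[[nm]] else rep(default, nrow(grid))
  }
  mu <- col("mu", learning_config()$mu)
  qv <- col("q", 6)
  li <- col("lambda_init", coupling_config()$lambda_init)
  lt <- col("lambda_trial", coupling_config()$lambda_trial)
  hi <- col("hi", criterion_config()$hi)
  lo <- col("lo", criterion_config()$lo)
  cons <- col("consecutive", criterion_config()$consecutive)
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- battery_config(
      tasks = tasks, n_seeds = n_seeds,
      learning = learning_config(mu = mu[g]),
      coupling = coupling_config(lambda_init = li[g], lambda_trial = lt[g]),
      criterion = criterion_config(hi = hi[g], lo = lo[g],
                                   consecutive = cons[g]),
      q = qv[g])
    res <- run_battery(cfg)
    merged <- merge(res, reference, by = c("task", "system", "phase"))
    scores[g] <- sum(abs(merged$trials_median - merged$trials) /
                       pmax(merged$trials, 1))
  }
  best <- which.min(scores)
  list(best = list(learning = learning_config(mu = mu[best]),
                   coupling = coupling_config(lambda_init = li[best],
                                              lambda_trial = lt[best]),
                   criterion = criterion_config(hi = hi[best], lo = lo[best],
                                                consecutive = cons[best]),
                   q = qv[best]),
       scores = cbind(grid, score = scores))
}
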