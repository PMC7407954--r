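# Plain-text checkpointing for reproducibility audits: every parameter
# matrix goes to one long-format CSV, the run configuration to a JSON
# manifest.

#' Save a model checkpoint
#'
#' Writes `params.csv` (columns `network`, `layer`, `matrix`, `row`,
#' `col`, `value`: one row per parameter entry) and `manifest.json`
#' (seeds, configuration, lesion flag, trial count) into `dir`.
#'
#' @param model A [chcq()] model.
#' @param dir Target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- function(network, layer, params) {
    do.call(rbind, lapply(c("W", "eps", "theta"), function(nm) {
      m <- params[[nm]]
      data.frame(network = network, layer = layer, matrix = nm,
                 row = as.vector(row(m)), col = as.vector(col(m)),
                 value = as.vector(m))
    }))
  }
  params <- rbind(
    flat("hippocampus", 1L, model$hippocampus$layer1),
    flat("hippocampus", 2L, model$hippocampus$layer2),
    flat("cortex", 1L, model$cortex$layer1),
    flat("cortex", 2L, model$cortex$layer2))
  utils::write.csv(params, file.path(dir, "params.csv"), row.names = FALSE)
  manifest <- list(r = model$r, q = model$q, lesioned = model$lesioned,
                   seed = model$seed, hip_seed = model$hip_seed,
                   n_trials = model$n_trials, n_reinits = model$n_reinits,
                   learning = unclass(model$learning),
                   coupling = unclass(model$coupling))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a model checkpoint
#'
#' Rebuilds a model from a directory written by [save_model()].  The
#' private noise stream restarts from the saved seed, so a reloaded model
#' reproduces a freshly built one only up to trial-time noise already
#' consumed.
#'
#' @param dir Directory containing `params.csv` and `manifest.json`.
#' @return A [chcq()] model.
#' @export
load_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  params <- utils::read.csv(file.path(dir, "params.csv"))
  model <- chcq(r = manifest$r, q = manifest$q,
                lesioned = manifest$lesioned,
                learning = do.call(learning_config, manifest$learning),
                coupling = do.call(coupling_config, manifest$coupling),
                seed = manifest$seed, hip_seed = manifest$hip_seed)
  unflat <- function(network, layer, target) {
    for (nm in c("W", "eps", "theta")) {
      sub <- params[params$network == network & params$layer == layer &
                      params$matrix == nm, ]
      m <- target[[nm]]
      m[cbind(sub$row, sub$col)] <- sub$value
      target[[nm]] <- m
    }
    target
  }
  model$hippocampus$layer1 <- unflat("hippocampus", 1L,
                                     model$hippocampus$layer1)
  model$hippocampus$layer2 <- unflat("hippocampus", 2L,
                                     model$hippocampus$layer2)
  model$cortex$layer1 <- unflat("cortex", 1L, model$cortex$layer1)
  model$cortex$layer2 <- unflat("cortex", 2L, model$cortex$layer2)
  model$n_trials <- manifest$n_trials
  model$n_reinits <- manifest$n_reinits
  model
}
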