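#' Read a run configuration from YAML
#'
#' Strict configuration loader: the file must contain the blocks `model`,
#' `solver`, `activity` and optionally `output`; unknown keys anywhere are
#' rejected with their location.  All lengths are in units of the coherence
#' length, times in units of the nematic relaxation time, and activities in
#' units of the passive stress scale.
#'
#' @param path YAML file path.
#' @return List of class `run_config` with `params` ([model_params()]),
#'   `cfg` ([solver_config()]), `pattern` ([activity_pattern()] or NULL)
#'   and `output` (list: `file`, `stride`).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("model", "solver", "activity", "output")
  check_keys(raw, known_top, "top level")
  model <- raw$model %||% list()
  check_keys(model, c("lambda", "l_eta", "gamma_tilde", "a2", "a4",
                      "elastic_K", "gamma_rot"), "model")
  params <- do.call(model_params, model)
  solver <- raw$solver %||% list()
  check_keys(solver, c("nx", "ny", "dx", "dt", "n_steps", "dealias", "seed",
                       "noise_amplitude"), "solver")
  cfg <- do.call(solver_config, solver)
  pattern <- if (is.null(raw$activity)) NULL else
    pattern_from_spec(raw$activity)
  output <- raw$output %||% list()
  check_keys(output, c("file", "stride"), "output")
  structure(list(params = params, cfg = cfg, pattern = pattern,
                 output = output, path = path),
            class = "run_config")
}

check_keys <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  invisible(x)
}

#' Build an activity pattern from a config list
#'
#' Dispatch on `kind`: tweezer, harmonic, strip, oscillating_strip,
#' traveling_strip, nucleation, superpose (with a `parts` list).
#'
#' @param spec Named list, e.g. parsed from the `activity:` YAML block.
#' @return An [activity_pattern()].
#' @export
pattern_from_spec <- function(spec) {
  kind <- spec$kind %||% stop("activity block needs a 'kind'")
  args <- spec[setdiff(names(spec), "kind")]
  switch(kind,
    tweezer = do.call(tweezer, args),
    harmonic = do.call(harmonic_disc, args),
    strip = do.call(strip, args),
    oscillating_strip = do.call(oscillating_strip, args),
    traveling_strip = do.call(traveling_strip, args),
    nucleation = do.call(nucleation_patch, args),
    superpose = superpose(lapply(spec$parts, pattern_from_spec)),
    stop("unknown activity kind: ", kind))
}

#' Save / load a simulation state
#'
#' Serializes the full state (Q components, activity sample, time, model
#' parameters and grid) with an embedded schema version and package
#' version; float64 payloads round-trip bit-exactly.
#'
#' @param state A [init_state()] result.
#' @param path Output path (`.rds`).
#' @return `save_state` returns `path` invisibly; `load_state` the restored
#'   `simulation_state`.
#' @export
save_state <- function(state, path) {
  obj <- list(schema = "actnem-state-1",
              version = as.character(utils::packageVersion("actnem")),
              time = state$time,
              qxx = state$q$qxx, qxy = state$q$qxy,
              alpha = state$alpha,
              grid = list(nx = state$q$grid$nx, ny = state$q$grid$ny,
                          dx = state$q$grid$dx),
              params = unclass(state$params)[c("lambda", "l_eta",
                                               "gamma_tilde", "a2", "a4",
                                               "elastic_K", "gamma_rot")])
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "actnem-state-1"))
    stop("unknown state schema version: ",
         obj$schema %||% "<missing>", " (no silent fallback)")
  g <- grid_spec(obj$grid$nx, obj$grid$ny, obj$grid$dx)
  params <- do.call(model_params, obj$params)
  st <- init_state(nematic_field(obj$qxx, obj$qxy, g), params,
                   time = obj$time)
  st$alpha <- obj$alpha
  st
}
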