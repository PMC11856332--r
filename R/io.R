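#' Write and read model parameters as YAML
#'
#' Parameters serialize to a flat key-value YAML file whose keys match the
#' [model_params()] field names exactly (with `alpha` as a length-3
#' sequence), so a saved file reconstructs the identical parameter set.
#'
#' @param params A [model_params()].
#' @param path File path.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns a validated `sirs_params`.
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- read_config_file(path)
  do.call(model_params, raw)
}

read_config_file <- function(path) {
  if (!file.exists(path))
    abort(sprintf("config file '%s' does not exist", path),
          class = "sirsmig_config_missing")
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    abort(sprintf("could not parse '%s': %s", path, conditionMessage(e)),
          class = "sirsmig_config_parse"))
  if (!is.list(raw))
    abort(sprintf("config '%s' must be a key-value mapping", path),
          class = "sirsmig_config_parse")
  raw
}

#' Write a trajectory to CSV (with a parameter sidecar)
#'
#' One row per recorded year with columns `year`, `Sr` ... `Rm`; the
#' parameters used are stored next to the table as `<stem>_params.yaml` so a
#' run can be reproduced bit-identically.
#'
#' @param traj A `sirs_trajectory`.
#' @param path CSV file path.
#' @param sidecar Write the parameter sidecar too (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, sidecar = TRUE) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  if (sidecar)
    write_params(trajectory_params(traj),
                 sub("\\.csv$", "_params.yaml", path))
  invisible(path)
}

#' @rdname write_trajectory
#' @param params Parameters to attach when reading (e.g. from the sidecar);
#'   optional.
#' @export
read_trajectory <- function(path, params = NULL) {
  df <- read.csv(path)
  if (!identical(names(df), c("year", COMPARTMENTS)))
    abort(sprintf("'%s' is not a trajectory table", path),
          class = "sirsmig_config_parse")
  structure(tibble::as_tibble(df),
            class = c("sirs_trajectory", class(tibble::tibble())),
            params = params, converged_year = NA_integer_)
}

#' Run configuration
#'
#' Validated bundle of everything a run needs: a named scenario or explicit
#' parameter overrides, the horizon, recording cadence, output directory and
#' sweep grids. Unknown keys in a config file are rejected by name so typos
#' cannot silently fall back to defaults.
#'
#' @param scenario Scenario name (see [list_scenarios()]), or `NULL` to
#'   build parameters from `params` overrides alone.
#' @param params Named list of [model_params()] overrides.
#' @param years,record_every Simulation horizon and recording cadence.
#' @param output_dir Where outputs are written.
#' @param mu_values,nu1_values,delta_I_values Sweep grids.
#' @param tol Bisection tolerance for boundary location.
#' @param early_stop Steady-state early stopping for sweeps.
#' @param plot Whether CLI commands also render figures.
#' @return A `sirs_run_config` list.
#' @export
run_config <- function(scenario = NULL, params = list(), years = NULL,
                       record_every = 1, output_dir = ".",
                       mu_values = NULL, nu1_values = NULL,
                       delta_I_values = NULL, tol = 1e-3,
                       early_stop = FALSE, plot = FALSE) {
  if (!is.list(params))
    abort("params overrides must be a named list", class = "sirsmig_invalid_config")
  base <- if (is.null(scenario)) model_params() else get_scenario(scenario)$params
  merged <- tryCatch(
    do.call(model_params, modifyList(param_fields(base), params)),
    sirsmig_invalid_params = function(e)
      abort(sprintf("invalid parameter override: %s", conditionMessage(e)),
            class = "sirsmig_invalid_config"))
  structure(list(scenario = scenario, params = merged, years = years,
                 record_every = record_every, output_dir = output_dir,
                 mu_values = mu_values, nu1_values = nu1_values,
                 delta_I_values = delta_I_values, tol = tol,
                 early_stop = early_stop, plot = plot),
            class = "sirs_run_config")
}

param_fields <- function(p) unclass(p)[names(unclass(p))]

#' Load a run configuration from YAML
#'
#' @param path Path to a YAML file; recognised keys are the arguments of
#'   [run_config()], with parameter overrides nested under `params`.
#' @return A validated `sirs_run_config`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("scenario: paper_default\nyears: 10", f)
#' load_config(f)$years
#' @export
load_config <- function(path) {
  raw <- read_config_file(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "sirsmig_invalid_config")
  if (!is.null(raw$params)) {
    pk <- setdiff(names(raw$params), names(formals(model_params)))
    if (length(pk) > 0)
      abort(sprintf("unknown parameter key(s): %s", paste(pk, collapse = ", ")),
            class = "sirsmig_invalid_config")
  }
  do.call(run_config, raw)
}

#' Save a run configuration to YAML
#'
#' @param config A `sirs_run_config`.
#' @param path File path.
#' @return `path`, invisibly. `load_config(write_config(x, f))` reproduces
#'   `x`'s parameters exactly.
#' @rdname load_config
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$params <- param_fields(config$params)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
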