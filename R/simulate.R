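#' Integrate one seasonal interval
#'
#' Advances the state under one of the two seasonal derivative fields using
#' an adaptive solver (deSolve's `lsoda`, relative tolerance `1e-8`,
#' absolute tolerance `1e-10` by default). The seasonal fields are smooth
#' and non-stiff at the default parameter scales; the migration pulses are
#' applied outside the integrator so no event handling is needed.
#'
#' Tiny negative components produced by solver round-off are clamped to zero
#' at the end of the interval; a negative excursion beyond `1e-8` is treated
#' as an integration failure rather than round-off and raises an error.
#'
#' @param state A [state_vector()].
#' @param field `"shared"` (Habitat 1 together) or `"separate"`.
#' @param duration Interval length in years, positive.
#' @param params A [model_params()].
#' @param rtol,atol Solver tolerances.
#' @param engine `"compiled"` (default) uses the C implementation of the
#'   derivative fields; `"r"` integrates the exported pure-R reference
#'   functions instead. Both must agree to solver tolerance.
#' @return The state at the end of the interval.
#' @export
integrate_interval <- function(state, field = c("shared", "separate"),
                               duration, params, rtol = 1e-8, atol = 1e-10,
                               engine = c("compiled", "r")) {
  field <- match.arg(field)
  engine <- match.arg(engine)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    abort("duration must be a positive number of years",
          class = "sirsmig_invalid_params")
  s <- as_state(state)

  sol <- if (engine == "compiled") {
    pvec <- c(params$b, params$d, params$sigma, params$gamma, params$mu,
              params$nu1, params$nu2, strain_betas(params), params$alpha)
    deSolve::ode(y = s, times = c(0, duration),
                 func = paste0("sirsmig_", field), parms = pvec,
                 dllname = "sirsmig", initfunc = "sirsmig_init",
                 rtol = rtol, atol = atol)
  } else {
    rhs <- if (field == "shared") rhs_shared_habitat else rhs_separate_habitats
    deSolve::ode(y = s, times = c(0, duration),
                 func = function(t, y, p) list(unname(rhs(y, p))),
                 parms = params, rtol = rtol, atol = atol)
  }
  if (attr(sol, "istate")[1] < 0)
    abort(sprintf("integration of the %s-season field failed (nu1=%g, mu=%g, delta_I=%g)",
                  field, params$nu1, params$mu, params$delta_I),
          class = "sirsmig_integration_error")
  out <- sol[nrow(sol), COMPARTMENTS]
  clamp_state(out, field, params)
}

# Zero out round-off negatives; anything more negative than -1e-8 signals a
# genuine solver failure and is escalated.
clamp_state <- function(s, field, params) {
  neg <- s < 0
  if (any(neg)) {
    worst <- min(s[neg])
    if (worst < -1e-8)
      abort(sprintf("solver produced a negative compartment (%.3e) in the %s season (nu1=%g, mu=%g)",
                    worst, field, params$nu1, params$mu),
            class = "sirsmig_integration_error")
    s[neg] <- 0
  }
  s
}

#' Advance the model by one annual cycle
#'
#' One year is, in order: integrate the shared-habitat field for `T1`, apply
#' the migration mortality pulse, integrate the separate-habitat field for
#' `T2`, and apply the pulse again as migrants return.
#'
#' @inheritParams integrate_interval
#' @return The state at the end of the year, after the second pulse.
#' @export
step_one_year <- function(state, params, rtol = 1e-8, atol = 1e-10,
                          engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  s <- integrate_interval(state, "shared", params$T1, params,
                          rtol = rtol, atol = atol, engine = engine)
  s <- apply_migration_pulse(s, params)
  s <- integrate_interval(s, "separate", params$T2, params,
                          rtol = rtol, atol = atol, engine = engine)
  apply_migration_pulse(s, params)
}

#' Run a multi-year simulation
#'
#' Iterates [step_one_year()] from an initial state, recording end-of-year
#' states (after the second migration pulse). The model is fully
#' deterministic. The default horizon is 2000 years with no early stopping;
#' for exploratory work `early_stop = TRUE` halts once the year-over-year
#' maximum relative change drops below `early_tol`, i.e. once the annual
#' return map has reached its fixed point.
#'
#' @param initial A [state_vector()], or a scenario from [paper_default()] /
#'   [limit_scenario()] (in which case its params, initial state and horizon
#'   are used unless overridden).
#' @param params A [model_params()]; ignored when `initial` is a scenario.
#' @param years Number of annual cycles to simulate.
#' @param record_every Record every `record_every`-th year (year 0 and the
#'   final simulated year are always recorded).
#' @param early_stop Stop once consecutive end-of-year states agree to
#'   `early_tol` relative. Off by default.
#' @param early_tol Relative-change threshold for `early_stop`.
#' @inheritParams integrate_interval
#' @return A `sirs_trajectory`: a tibble with columns `year`, `Sr` ... `Rm`,
#'   carrying the parameters as an attribute. The attribute
#'   `converged_year` holds the year at which early stopping triggered, or
#'   `NA` if it did not (or was off).
#' @examples
#' \donttest{
#' traj <- run_simulation(paper_default(), years = 50)
#' tail(traj)
#' }
#' @export
run_simulation <- function(initial, params = NULL, years = NULL,
                           record_every = 1, early_stop = FALSE,
                           early_tol = 1e-10, rtol = 1e-8, atol = 1e-10,
                           engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  if (inherits(initial, "sirs_scenario")) {
    if (is.null(params)) params <- initial$params
    if (is.null(years)) years <- initial$years
    initial <- initial$initial
  }
  if (is.null(params)) abort("params must be supplied",
                             class = "sirsmig_invalid_params")
  if (is.null(years)) years <- 2000
  if (years < 1) abort("years must be at least 1",
                       class = "sirsmig_invalid_params")
  record_every <- max(1L, as.integer(record_every))
  s <- as_state(initial)

  rec_years <- integer(0)
  rec_states <- list()
  record <- function(y, st) {
    rec_years[[length(rec_years) + 1L]] <<- y
    rec_states[[length(rec_states) + 1L]] <<- st
  }
  record(0L, s)
  converged <- NA_integer_
  for (y in seq_len(years)) {
    s_new <- step_one_year(s, params, rtol = rtol, atol = atol, engine = engine)
    if (y %% record_every == 0L || y == years) record(y, s_new)
    if (early_stop) {
      scale <- max(max(abs(s_new)), 1e-8)
      if (max(abs(s_new - s)) / scale < early_tol) {
        converged <- y
        if (y %% record_every != 0L && y != years) record(y, s_new)
        s <- s_new
        break
      }
    }
    s <- s_new
  }

  new_trajectory(rec_years, rec_states, params, converged)
}

new_trajectory <- function(years, states, params, converged_year = NA_integer_) {
  m <- do.call(rbind, states)
  colnames(m) <- COMPARTMENTS
  out <- tibble::as_tibble(as.data.frame(m))
  out <- dplyr::bind_cols(tibble::tibble(year = as.integer(years)), out)
  structure(out,
            class = c("sirs_trajectory", class(tibble::tibble())),
            params = params, converged_year = converged_year)
}

#' Final recorded state of a trajectory
#'
#' @param traj A `sirs_trajectory` from [run_simulation()].
#' @return A [state_vector()] for the last recorded year.
#' @export
final_state <- function(traj) {
  if (!inherits(traj, "sirs_trajectory") || nrow(traj) == 0)
    abort("traj must be a non-empty sirs_trajectory",
          class = "sirsmig_invalid_state")
  last <- unlist(traj[nrow(traj), COMPARTMENTS], use.names = FALSE)
  setNames(as.numeric(last), COMPARTMENTS)
}

# Parameters a trajectory was produced with.
trajectory_params <- function(traj) attr(traj, "params")
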