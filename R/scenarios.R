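#' Named simulation scenarios
#'
#' A scenario bundles a parameter set, an initial state and a horizon so
#' every configuration the analysis exercises can be reconstructed by name,
#' with no external input. All scenarios are deterministic.
#'
#' @name scenarios
NULL

new_scenario <- function(name, params, initial, years, description = "") {
  structure(list(name = name, params = params, initial = as_state(initial),
                 years = years, description = description),
            class = "sirs_scenario")
}

#' @export
print.sirs_scenario <- function(x, ...) {
  cat(sprintf("<sirs_scenario> %s (%d years, N0 = %g)\n%s\n",
              x$name, x$years, sum(x$initial), x$description))
  invisible(x)
}

#' Default single-run scenario
#'
#' The standard parameterization: table defaults with `mu = 0`,
#' `nu1 = 0.14` (so `nu2 = 0.26`) and migratory culling `delta_I = 4 *
#' delta_S = 0.004`; 100 individuals in each of the 10 classes (1,000
#' total) and a 2000-year horizon.
#'
#' @return A `sirs_scenario`.
#' @examples
#' sc <- paper_default()
#' total_population(sc$initial)
#' @rdname scenarios
#' @export
paper_default <- function() {
  new_scenario(
    "paper_default",
    model_params(mu = 0, nu1 = 0.14, delta_I = 0.004),
    setNames(rep(100, 10), COMPARTMENTS),
    years = 2000,
    description = "Reference run: SIR limit (mu = 0), nu1 = 0.14, delta_I = 4 delta_S."
  )
}

#' Limiting-case scenarios
#'
#' Degenerate corners of the SIRS model: `"SI"` removes recovery
#' (`nu1 = nu2 = 0`, hosts never leave the infected classes), `"SIR"`
#' removes immunity loss (`mu = 0`), `"SIS"` makes immunity loss fast
#' relative to every other rate (`mu = 20`, mean immune residence 0.05
#' years, a finite stand-in for instantaneous return to susceptibility) and
#' `"disease_free"` starts with no infected or resistant hosts.
#'
#' @param kind One of `"SI"`, `"SIR"`, `"SIS"`, `"disease_free"`.
#' @return A `sirs_scenario`.
#' @rdname scenarios
#' @export
limit_scenario <- function(kind = c("SI", "SIR", "SIS", "disease_free")) {
  if (!is.character(kind) || length(kind) != 1L ||
      !kind %in% c("SI", "SIR", "SIS", "disease_free"))
    abort("kind must be one of SI, SIR, SIS, disease_free",
          class = "sirsmig_invalid_params")
  full <- setNames(rep(100, 10), COMPARTMENTS)
  switch(kind,
    SI = new_scenario("SI", model_params(nu1 = 0, nu2 = 0, mu = 0), full, 2000,
                      "No recovery: infection is lifelong."),
    SIR = new_scenario("SIR", model_params(mu = 0), full, 2000,
                       "Permanent immunity: no return from R to S."),
    SIS = new_scenario("SIS", model_params(mu = 20), full, 2000,
                       "Fast immunity loss: R is a brief waypoint back to S."),
    disease_free = new_scenario(
      "disease_free", model_params(),
      state_vector(Sr = 100, Sm = 100), 2000,
      "Residents and migrants with no pathogen; pure demography.")
  )
}

#' Desk-scale sweep grid
#'
#' A 6 x 6 grid over the immunity-loss rate `mu` in `[0, 1]` and the
#' Habitat 1 recovery rate `nu1` in `[0, 0.5]`, with migratory culling
#' levels `delta_I` at 1, 4 and 8 times `delta_S`. The grid spans the SIR
#' (`mu = 0`) and SI (`nu1 = 0`) edges and is sized so a full sweep runs in
#' minutes on one core.
#'
#' @return A list with `mu_values`, `nu1_values` and `delta_I_values`.
#' @rdname scenarios
#' @export
reduced_grid <- function() {
  dS <- 0.001
  list(mu_values = seq(0, 1, length.out = 6),
       nu1_values = seq(0, 0.5, length.out = 6),
       delta_I_values = dS * c(1, 4, 8))
}

#' List the named scenarios
#'
#' @return A tibble with scenario names and descriptions.
#' @rdname scenarios
#' @export
list_scenarios <- function() {
  scs <- c(list(paper_default()),
           lapply(c("SI", "SIR", "SIS", "disease_free"), limit_scenario))
  tibble::tibble(
    name = vapply(scs, `[[`, "", "name"),
    years = vapply(scs, `[[`, 0, "years"),
    initial_N = vapply(scs, function(s) sum(s$initial), 0),
    description = vapply(scs, `[[`, "", "description")
  )
}

# Resolve a scenario by name, e.g. from a config file or the CLI.
get_scenario <- function(name) {
  if (name == "paper_default") return(paper_default())
  if (name %in% c("SI", "SIR", "SIS", "disease_free"))
    return(limit_scenario(name))
  abort(sprintf("unknown scenario '%s'; see list_scenarios()", name),
        class = "sirsmig_invalid_config")
}
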