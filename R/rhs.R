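#' Derivative field for the shared-habitat season
#'
#' During the first part of the year migrants and residents occupy Habitat 1
#' together. Susceptibles of either host type are infected by the pooled
#' infecteds of both types at strain-specific rates `beta_i`; immunity is
#' lost at rate `mu`; reproduction (into each type's own susceptible class)
#' is density dependent through the factor `1 - gamma * N`, with infected
#' parents reproducing at the reduced rate `b + sigma`; both host types
#' recover at the Habitat 1 rate `nu1`; background mortality is `d` and
#' infecteds die additionally at their strain's virulence `alpha_i`.
#'
#' This pure-R form is the reference definition of the model; the integrator
#' uses an equivalent compiled version, and the two are held to exact
#' agreement in the test suite.
#'
#' @param state A [state_vector()].
#' @param params A [model_params()].
#' @return Named numeric vector of the 10 time derivatives (per year).
#' @seealso [rhs_separate_habitats()], [apply_migration_pulse()]
#' @export
rhs_shared_habitat <- function(state, params) {
  s <- as_state(state)
  beta <- strain_betas(params)
  N <- sum(s)
  f <- 1 - params$gamma * N
  Ir <- s[c("Ir1", "Ir2", "Ir3")]
  Im <- s[c("Im1", "Im2", "Im3")]
  pool <- Ir + Im
  foi <- sum(beta * pool)

  d <- numeric(10)
  names(d) <- COMPARTMENTS
  d["Sr"] <- -s["Sr"] * foi + params$mu * s["Rr"] +
    (params$b * (s["Sr"] + s["Rr"]) + (params$b + params$sigma) * sum(Ir)) * f -
    params$d * s["Sr"]
  d["Sm"] <- -s["Sm"] * foi + params$mu * s["Rm"] +
    (params$b * (s["Sm"] + s["Rm"]) + (params$b + params$sigma) * sum(Im)) * f -
    params$d * s["Sm"]
  d[c("Ir1", "Ir2", "Ir3")] <- beta * s["Sr"] * pool - params$nu1 * Ir -
    (params$d + params$alpha) * Ir
  d[c("Im1", "Im2", "Im3")] <- beta * s["Sm"] * pool - params$nu1 * Im -
    (params$d + params$alpha) * Im
  d["Rr"] <- params$nu1 * sum(Ir) - (params$mu + params$d) * s["Rr"]
  d["Rm"] <- params$nu1 * sum(Im) - (params$mu + params$d) * s["Rm"]
  d
}

#' Derivative field for the separate-habitat season
#'
#' During the second part of the year migrants are in Habitat 2 and
#' residents in Habitat 1. There is no reproduction; transmission is
#' within host type only; residents recover at `nu1` while migrants enjoy
#' migratory recovery at the higher rate `nu2`.
#'
#' @inheritParams rhs_shared_habitat
#' @return Named numeric vector of the 10 time derivatives (per year).
#' @export
rhs_separate_habitats <- function(state, params) {
  s <- as_state(state)
  beta <- strain_betas(params)
  Ir <- s[c("Ir1", "Ir2", "Ir3")]
  Im <- s[c("Im1", "Im2", "Im3")]

  d <- numeric(10)
  names(d) <- COMPARTMENTS
  d["Sr"] <- -s["Sr"] * sum(beta * Ir) + params$mu * s["Rr"] - params$d * s["Sr"]
  d["Sm"] <- -s["Sm"] * sum(beta * Im) + params$mu * s["Rm"] - params$d * s["Sm"]
  d[c("Ir1", "Ir2", "Ir3")] <- beta * s["Sr"] * Ir - params$nu1 * Ir -
    (params$d + params$alpha) * Ir
  d[c("Im1", "Im2", "Im3")] <- beta * s["Sm"] * Im - params$nu2 * Im -
    (params$d + params$alpha) * Im
  d["Rr"] <- params$nu1 * sum(Ir) - (params$mu + params$d) * s["Rr"]
  d["Rm"] <- params$nu2 * sum(Im) - (params$mu + params$d) * s["Rm"]
  d
}

#' Pulsed migration mortality
#'
#' Each migration event (twice a year, at the season boundaries) kills a
#' fixed fraction of each migrant class: susceptible migrants are multiplied
#' by `1 - delta_S`, each infected migrant class by `1 - delta_I`, and
#' resistant migrants by `1 - delta_R`. The five resident classes are
#' unchanged. Migratory culling corresponds to `delta_I` exceeding
#' `delta_S` and `delta_R`.
#'
#' @inheritParams rhs_shared_habitat
#' @return The post-migration state vector.
#' @export
apply_migration_pulse <- function(state, params) {
  s <- as_state(state)
  s["Sm"] <- (1 - params$delta_S) * s["Sm"]
  s[c("Im1", "Im2", "Im3")] <- (1 - params$delta_I) * s[c("Im1", "Im2", "Im3")]
  s["Rm"] <- (1 - params$delta_R) * s["Rm"]
  s
}
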