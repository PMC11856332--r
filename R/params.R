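#' Model parameters for the partially migratory multi-strain SIRS model
#'
#' Bundles every constant of the model: the annual-cycle split, demography,
#' the three strain virulences, migration mortality fractions, immunity loss,
#' habitat-specific recovery rates, and the transmission-virulence trade-off
#' constants. All rates are per year; one simulated year has length 1 and is
#' split into a shared-habitat season of length `T1` followed by a
#' separate-habitat season of length `T2`.
#'
#' Defaults are the model's standard parameterization, with the commonly
#' varied quantities (`mu`, `nu1`, `delta_I`) set to the values of the
#' reference single-run example (`mu = 0`, `nu1 = 0.14`, `delta_I = 0.004`).
#'
#' @param T1 Fraction of the year migrants and residents share Habitat 1.
#' @param T2 Fraction of the year they are apart; `T1 + T2` must equal 1.
#' @param b Density-independent birth rate (per year).
#' @param d Pathogen-independent mortality rate (per year).
#' @param alpha Numeric vector of the three strictly increasing
#'   disease-induced mortality rates (virulences), per year.
#' @param sigma Disease-induced fecundity cost, stored signed and added to
#'   `b` for infected parents (so the default `-0.02` reduces their birth
#'   rate to `b + sigma = 1.98`).
#' @param gamma Density-dependence strength (per individual); the birth term
#'   carries a factor `1 - gamma * N` so the carrying capacity is `1/gamma`.
#' @param delta_S,delta_I,delta_R Per-migration-event mortality fractions in
#'   `[0, 1)` for susceptible, infected and resistant migrants.
#' @param mu Immunity-loss rate (per year); `mu = 0` gives an SIR model.
#' @param nu1 Recovery rate in Habitat 1 (per year).
#' @param nu2 Recovery rate in Habitat 2 (per year); `NULL` (default) sets
#'   the standard offset `nu1 + 0.12` implementing migratory recovery.
#' @param cA,cB Trade-off constants, see [transmission_rate()].
#' @param tradeoff_form Functional form linking transmission to virulence:
#'   `"concave_sqrt"` (default, `cA * sqrt(cB + alpha)`), `"ratio"`
#'   (`cA / (cB + alpha)`) or `"linear"` (`cA * cB + alpha`).
#'
#' @return An object of class `sirs_params` (a validated named list).
#' @examples
#' p <- model_params()
#' p$nu2 # 0.26
#' transmission_rate(p$alpha, p)
#' @export
model_params <- function(T1 = 0.5, T2 = 0.5, b = 2, d = 0.14,
                         alpha = c(0.01, 0.05, 0.1), sigma = -0.02,
                         gamma = 1e-4, delta_S = 0.001, delta_I = 0.004,
                         delta_R = 0.001, mu = 0, nu1 = 0.14, nu2 = NULL,
                         cA = 0.005, cB = 0.14,
                         tradeoff_form = c("concave_sqrt", "ratio", "linear")) {
  tradeoff_form <- match.arg(tradeoff_form)
  if (is.null(nu2)) nu2 <- nu1 + 0.12
  p <- list(T1 = T1, T2 = T2, b = b, d = d, alpha = as.numeric(alpha),
            sigma = sigma, gamma = gamma, delta_S = delta_S,
            delta_I = delta_I, delta_R = delta_R, mu = mu, nu1 = nu1,
            nu2 = nu2, cA = cA, cB = cB, tradeoff_form = tradeoff_form)
  validate_params(p)
  structure(p, class = "sirs_params")
}

validate_params <- function(p) {
  bad <- function(msg) abort(msg, class = "sirsmig_invalid_params")
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("T1", "T2", "b", "d", "sigma", "gamma", "delta_S", "delta_I",
              "delta_R", "mu", "nu1", "nu2", "cA", "cB")) {
    if (!num1(p[[f]])) bad(sprintf("parameter '%s' must be a single finite number", f))
  }
  if (abs(p$T1 + p$T2 - 1) > 1e-12)
    bad(sprintf("T1 + T2 must equal 1 (got %g + %g = %g)",
                p$T1, p$T2, p$T1 + p$T2))
  if (p$T1 <= 0 || p$T2 <= 0) bad("season lengths T1 and T2 must be positive")
  if (length(p$alpha) != 3L || any(!is.finite(p$alpha)))
    bad("alpha must be three finite virulence rates")
  if (any(diff(p$alpha) <= 0)) bad("alpha must be strictly increasing")
  if (any(p$alpha < 0)) bad("alpha rates must be non-negative")
  for (f in c("b", "d", "gamma", "mu", "nu1", "nu2"))
    if (p[[f]] < 0) bad(sprintf("parameter '%s' must be non-negative", f))
  for (f in c("delta_S", "delta_I", "delta_R"))
    if (p[[f]] < 0 || p[[f]] >= 1)
      bad(sprintf("parameter '%s' must lie in [0, 1)", f))
  if (p$cA < 0) bad("cA must be non-negative")
  if (p$cB < 0) bad("cB must be non-negative")
  if (p$b + p$sigma < 0) bad("infected birth rate b + sigma must be non-negative")
  invisible(p)
}

#' @export
print.sirs_params <- function(x, ...) {
  cat("<sirs_params>\n")
  cat(sprintf("  seasons      T1 = %g, T2 = %g\n", x$T1, x$T2))
  cat(sprintf("  demography   b = %g, d = %g, sigma = %g, gamma = %g (K = %g)\n",
              x$b, x$d, x$sigma, x$gamma, 1 / x$gamma))
  cat(sprintf("  virulence    alpha = (%s)\n", paste(x$alpha, collapse = ", ")))
  cat(sprintf("  trade-off    %s with cA = %g, cB = %g -> beta = (%s)\n",
              x$tradeoff_form, x$cA, x$cB,
              paste(signif(transmission_rate(x$alpha, x), 5), collapse = ", ")))
  cat(sprintf("  recovery     nu1 = %g, nu2 = %g; immunity loss mu = %g\n",
              x$nu1, x$nu2, x$mu))
  cat(sprintf("  migration    delta_S = %g, delta_I = %g, delta_R = %g\n",
              x$delta_S, x$delta_I, x$delta_R))
  invisible(x)
}

#' Transmission rate implied by the virulence trade-off
#'
#' Maps a strain's disease-induced mortality rate (virulence) to its
#' per-susceptible, per-infected transmission rate. Under the default
#' `"concave_sqrt"` form, `beta = cA * sqrt(cB + alpha)`, transmission is
#' strictly increasing and concave down in virulence, so each extra unit of
#' virulence buys a smaller gain in transmission. The `"ratio"`
#' (`cA / (cB + alpha)`) and `"linear"` (`cA * cB + alpha`) forms are
#' available for sensitivity analysis.
#'
#' @param alpha_i Virulence rate(s), per year; non-negative.
#' @param params A [model_params()] object supplying `cA`, `cB` and
#'   `tradeoff_form`.
#' @return Transmission rate(s), per year per individual, same length as
#'   `alpha_i`.
#' @examples
#' transmission_rate(0.01, model_params()) # 0.005 * sqrt(0.15)
#' @export
transmission_rate <- function(alpha_i, params) {
  if (any(!is.finite(alpha_i)) || any(alpha_i < 0))
    abort("virulence alpha_i must be finite and non-negative",
          class = "sirsmig_invalid_params")
  if (params$cA < 0 || params$cB < 0)
    abort("trade-off constants cA, cB must be non-negative",
          class = "sirsmig_invalid_params")
  switch(params$tradeoff_form,
    concave_sqrt = params$cA * sqrt(params$cB + alpha_i),
    ratio = {
      if (any(params$cB + alpha_i <= 0))
        abort("ratio trade-off requires cB + alpha > 0",
              class = "sirsmig_invalid_params")
      params$cA / (params$cB + alpha_i)
    },
    linear = params$cA * params$cB + alpha_i,
    abort(sprintf("unknown tradeoff_form '%s'", params$tradeoff_form),
          class = "sirsmig_invalid_params")
  )
}

# beta1..beta3 for the three strains under the configured trade-off.
strain_betas <- function(params) transmission_rate(params$alpha, params)
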