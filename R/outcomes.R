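#' Winning pathogen strategy
#'
#' The winning strain is the one whose pooled infected compartments
#' (residents plus migrants) form the largest share of the final population.
#' Because the losing strategies decay towards zero but never reach it in a
#' continuous-state model, a strain whose pooled total is below `threshold`
#' is treated as absent; if all three are, the pathogen is extinct. Ties are
#' broken towards the lower (less virulent) strain index.
#'
#' @param final A [state_vector()], typically [final_state()] of a run.
#' @param threshold Extinction threshold in individuals (default `1e-6`).
#' @return Integer 1, 2 or 3, or `NA_integer_` when the pathogen is extinct.
#' @export
winning_strain <- function(final, threshold = 1e-6) {
  if (threshold < 0) abort("threshold must be non-negative",
                           class = "sirsmig_invalid_params")
  tot <- strain_totals(final)
  if (max(tot) < threshold) return(NA_integer_)
  near <- which(tot >= max(tot) * (1 - 1e-9))
  if (length(near) > 1L)
    warn("near-tie between strains; reporting the least virulent",
         class = "sirsmig_tie")
  which.max(tot)
}

#' Do migrants outnumber residents?
#'
#' Compares the five migrant compartments with the five resident
#' compartments. An exact tie (including the all-zero state) is reported as
#' resident dominance, since any positive migration mortality strictly
#' shrinks an otherwise symmetric migrant pool.
#'
#' @inheritParams winning_strain
#' @return `TRUE` when migrants strictly outnumber residents.
#' @export
host_strategy_dominance <- function(final) {
  s <- as_state(final)
  migrant <- sum(s[MIGRANT_CLASSES])
  resident <- sum(s) - migrant
  if (migrant > 0 && abs(migrant - resident) <= 1e-9 * max(migrant, resident))
    warn("migrant and resident totals are within 1e-9 relative",
         class = "sirsmig_tie")
  migrant > resident
}

#' Summarise a simulation run
#'
#' Applies [winning_strain()] and [host_strategy_dominance()] to the final
#' recorded state of a trajectory and collects per-strain and per-host-type
#' totals.
#'
#' @param traj A `sirs_trajectory` from [run_simulation()].
#' @param threshold Extinction threshold passed to [winning_strain()].
#' @return A `sirs_outcome` list with elements `winner` (integer or `NA` for
#'   extinct), `strain_totals`, `migrant_total`, `resident_total`,
#'   `migrants_dominate`, `final_N`, `final_year`, and the run's `params`.
#' @export
summarize_outcome <- function(traj, threshold = 1e-6) {
  final <- final_state(traj)
  migrant <- sum(final[MIGRANT_CLASSES])
  structure(list(
    winner = winning_strain(final, threshold),
    strain_totals = strain_totals(final),
    migrant_total = migrant,
    resident_total = sum(final) - migrant,
    migrants_dominate = host_strategy_dominance(final),
    final_N = sum(final),
    final_year = traj$year[nrow(traj)],
    params = trajectory_params(traj)
  ), class = "sirs_outcome")
}

#' @export
print.sirs_outcome <- function(x, ...) {
  cat("<sirs_outcome>\n")
  cat(sprintf("  winner: %s  (strain totals: %s)\n",
              if (is.na(x$winner)) "extinct" else paste0("strain ", x$winner),
              paste(signif(x$strain_totals, 4), collapse = ", ")))
  cat(sprintf("  hosts:  %s dominate (migrants %.4g vs residents %.4g)\n",
              if (x$migrants_dominate) "migrants" else "residents",
              x$migrant_total, x$resident_total))
  cat(sprintf("  final population N = %.6g at year %d\n", x$final_N,
              x$final_year))
  invisible(x)
}

#' Tidy a simulation outcome into a one-row tibble
#'
#' @param x A `sirs_outcome` from [summarize_outcome()].
#' @param ... Unused.
#' @return A tibble with one row: the varied parameters (`mu`, `nu1`,
#'   `delta_I`), the winner, per-strain totals, host-type totals and final
#'   population size.
#' @export
tidy.sirs_outcome <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    mu = p$mu, nu1 = p$nu1, delta_I = p$delta_I,
    winner = x$winner,
    strain1_total = x$strain_totals[1],
    strain2_total = x$strain_totals[2],
    strain3_total = x$strain_totals[3],
    migrant_total = x$migrant_total,
    resident_total = x$resident_total,
    migrants_dominate = x$migrants_dominate,
    final_N = x$final_N
  )
}

#' One-line model-level summary of an outcome
#'
#' @inheritParams tidy.sirs_outcome
#' @return A one-row tibble with the winner, extinction flag, dominance and
#'   final population.
#' @export
glance.sirs_outcome <- function(x, ...) {
  tibble::tibble(
    winner = x$winner,
    pathogen_extinct = is.na(x$winner),
    migrants_dominate = x$migrants_dominate,
    final_N = x$final_N,
    final_year = x$final_year
  )
}

#' Long-format view of a trajectory
#'
#' @param x A `sirs_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `year`, `compartment`, `host` (resident /
#'   migrant), `class` (S, I1, I2, I3, R) and `count`.
#' @export
tidy.sirs_trajectory <- function(x, ...) {
  out <- tidyr::pivot_longer(tibble::as_tibble(x), -"year",
                             names_to = "compartment", values_to = "count")
  out$host <- ifelse(out$compartment %in% MIGRANT_CLASSES, "migrant", "resident")
  out$class <- sub("^([SIR])([rm])([0-9]?)$", "\\1\\3", out$compartment)
  out[c("year", "compartment", "host", "class", "count")]
}
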