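#' Phase map of the winning pathogen strategy
#'
#' Runs the full three-strain competition at every point of a grid over the
#' immunity-loss rate `mu` and the Habitat 1 recovery rate `nu1`, holding
#' `delta_I` fixed, and records which strain wins and whether migrants
#' outnumber residents. Each cell starts from 100 individuals in every
#' class, and `nu2` follows `nu1` as `nu1 + 0.12`. Cells are independent of
#' one another, so the grid may be evaluated in any order.
#'
#' @param mu_values,nu1_values Strictly increasing grids of rates (per year).
#' @param delta_I Infected migration mortality fraction for the whole map.
#' @param base A [model_params()] supplying every non-varied constant.
#' @param years Simulation horizon per cell.
#' @param early_stop,early_tol Optional steady-state early stopping (see
#'   [run_simulation()]); leave off to reproduce the full-horizon analysis.
#' @param threshold Extinction threshold for [winning_strain()].
#' @param rtol,atol Solver tolerances.
#' @return A `sirs_phase_map` tibble with one row per cell: `mu`, `nu1`,
#'   `delta_I`, `winner` (integer, `NA` = pathogen extinct), per-strain
#'   totals, `migrants_dominate` and `final_N`.
#' @examples
#' \donttest{
#' pm <- phase_map(c(0, 0.5), c(0, 0.3), delta_I = 0.004, years = 200,
#'                 early_stop = TRUE)
#' }
#' @export
phase_map <- function(mu_values, nu1_values, delta_I,
                      base = model_params(), years = 2000,
                      early_stop = FALSE, early_tol = 1e-10,
                      threshold = 1e-6, rtol = 1e-8, atol = 1e-10) {
  check_grid(mu_values, "mu_values")
  check_grid(nu1_values, "nu1_values")
  cells <- tidyr::expand_grid(nu1 = nu1_values, mu = mu_values)
  rows <- purrr::pmap(cells, function(nu1, mu) {
    out <- competition_outcome(mu, nu1, delta_I, base, years,
                               early_stop, early_tol, threshold, rtol, atol)
    tidy(out)
  })
  res <- dplyr::bind_rows(rows)
  structure(res,
            class = c("sirs_phase_map", class(tibble::tibble())),
            base_params = base, delta_I = delta_I, years = years)
}

check_grid <- function(x, what) {
  if (length(x) < 1L || any(!is.finite(x)) || is.unsorted(x, strictly = TRUE))
    abort(sprintf("%s must be a non-empty strictly increasing grid", what),
          class = "sirsmig_invalid_params")
}

# One competition run at a (mu, nu1, delta_I) coordinate from the standard
# 100-per-class initial condition, with nu2 tracking nu1.
competition_outcome <- function(mu, nu1, delta_I, base, years,
                                early_stop = FALSE, early_tol = 1e-10,
                                threshold = 1e-6, rtol = 1e-8, atol = 1e-10) {
  p <- base
  p$mu <- mu
  p$nu1 <- nu1
  p$nu2 <- nu1 + 0.12
  p$delta_I <- delta_I
  validate_params(p)
  traj <- tryCatch(
    run_simulation(setNames(rep(100, 10), COMPARTMENTS), p, years = years,
                   record_every = years, early_stop = early_stop,
                   early_tol = early_tol, rtol = rtol, atol = atol),
    sirsmig_integration_error = function(e)
      abort(sprintf("phase-map cell (mu=%g, nu1=%g, delta_I=%g) failed: %s",
                    mu, nu1, delta_I, conditionMessage(e)),
            class = "sirsmig_integration_error")
  )
  summarize_outcome(traj, threshold)
}

#' Winner-transition boundaries along the recovery rate
#'
#' For each immunity-loss rate `mu`, locates by bisection the smallest
#' Habitat 1 recovery rate `nu1` at which the winning strain switches from
#' strain 1 to strain 2 and from strain 2 to strain 3. A coarse pre-scan
#' over `nu1_range` verifies that the winner index is non-decreasing in
#' `nu1` (the expected structure under the concave trade-off); if it is not,
#' the function falls back to a dense scan at resolution `tol` and warns.
#' Where a switch does not occur inside `nu1_range` the threshold is `NA`.
#'
#' @param mu_values Immunity-loss rates to profile.
#' @param delta_I Infected migration mortality fraction.
#' @param nu1_range Length-2 interval searched for transitions.
#' @param base,years,early_stop,early_tol,threshold,rtol,atol As in
#'   [phase_map()].
#' @param tol Bisection tolerance on `nu1`.
#' @param scan_points Number of pre-scan points across `nu1_range`.
#' @return A `sirs_transition_curve` tibble with columns `mu`, `delta_I`,
#'   `nu1_1to2` and `nu1_2to3`.
#' @export
transition_boundaries <- function(mu_values, delta_I, nu1_range = c(0, 0.5),
                                  base = model_params(), years = 2000,
                                  tol = 1e-3, scan_points = 6,
                                  early_stop = FALSE, early_tol = 1e-10,
                                  threshold = 1e-6, rtol = 1e-8, atol = 1e-10) {
  check_grid(mu_values, "mu_values")
  if (length(nu1_range) != 2L || nu1_range[1] < 0 || diff(nu1_range) <= 0)
    abort("nu1_range must be a positive interval", class = "sirsmig_invalid_params")
  if (tol <= 0) abort("tol must be positive", class = "sirsmig_invalid_params")

  winner_at <- function(mu, nu1)
    competition_outcome(mu, nu1, delta_I, base, years, early_stop, early_tol,
                        threshold, rtol, atol)$winner

  one_mu <- function(mu) {
    grid <- seq(nu1_range[1], nu1_range[2], length.out = scan_points)
    w <- vapply(grid, function(v) {
      wi <- winner_at(mu, v)
      if (is.na(wi)) 0L else wi
    }, integer(1))
    defined <- w > 0L
    if (any(diff(w[defined]) < 0L)) {
      warn(sprintf("winner not monotone along nu1 at mu = %g; using dense scan", mu),
           class = "sirsmig_nonmonotone")
      grid <- seq(nu1_range[1], nu1_range[2], by = tol)
      w <- vapply(grid, function(v) {
        wi <- winner_at(mu, v)
        if (is.na(wi)) 0L else wi
      }, integer(1))
    }
    find <- function(target) {
      # smallest nu1 whose winner index reaches `target`
      hi_idx <- which(w >= target & w > 0L)
      lo_idx <- which(w < target & w > 0L)
      if (length(hi_idx) == 0L || length(lo_idx) == 0L) return(NA_real_)
      hi <- grid[min(hi_idx)]
      below <- grid[lo_idx][grid[lo_idx] < hi]
      if (length(below) == 0L) return(NA_real_)
      lo <- max(below)
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        wm <- winner_at(mu, mid)
        if (!is.na(wm) && wm >= target) hi <- mid else lo <- mid
      }
      hi
    }
    tibble::tibble(mu = mu, delta_I = delta_I,
                   nu1_1to2 = find(2L), nu1_2to3 = find(3L))
  }

  res <- dplyr::bind_rows(lapply(mu_values, one_mu))
  structure(res,
            class = c("sirs_transition_curve", class(tibble::tibble())),
            base_params = base, years = years, tol = tol,
            nu1_range = nu1_range)
}
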