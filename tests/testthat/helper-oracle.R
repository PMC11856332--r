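# Independent oracles, coded directly from the model equations and kept
# separate from the package's implementation path.
#
# * oracle_rhs_shared / oracle_rhs_separate: term-by-term transcriptions of
#   the two seasonal derivative fields.
# * rk4_integrate / oracle_one_year: fixed-step classical Runge-Kutta
#   integration of those fields with the migration pulses applied at the
#   season boundaries.
# * run_sis_oracle: an 8-compartment SIS variant (no resistant classes,
#   recovery routed straight back to S) for the fast-immunity-loss limit.

ORACLE_ORDER <- c("Sr", "Ir1", "Ir2", "Ir3", "Rr",
                  "Sm", "Im1", "Im2", "Im3", "Rm")

oracle_beta <- function(p) p$cA * sqrt(p$cB + p$alpha)

oracle_rhs_shared <- function(y, p) {
  b <- oracle_beta(p)
  N <- sum(y)
  Sr <- y[1]; Ir <- y[2:4]; Rr <- y[5]
  Sm <- y[6]; Im <- y[7:9]; Rm <- y[10]
  dSr <- sum(-Sr * b * (Ir + Im)) + p$mu * Rr +
    (p$b * (Sr + Rr) + (p$b + p$sigma) * sum(Ir)) * (1 - p$gamma * N) - p$d * Sr
  dSm <- sum(-Sm * b * (Ir + Im)) + p$mu * Rm +
    (p$b * (Sm + Rm) + (p$b + p$sigma) * sum(Im)) * (1 - p$gamma * N) - p$d * Sm
  dIr <- b * Sr * (Ir + Im) - p$nu1 * Ir - (p$d + p$alpha) * Ir
  dIm <- b * Sm * (Ir + Im) - p$nu1 * Im - (p$d + p$alpha) * Im
  dRr <- p$nu1 * sum(Ir) - p$mu * Rr - p$d * Rr
  dRm <- p$nu1 * sum(Im) - p$mu * Rm - p$d * Rm
  c(dSr, dIr, dRr, dSm, dIm, dRm)
}

oracle_rhs_separate <- function(y, p) {
  b <- oracle_beta(p)
  Sr <- y[1]; Ir <- y[2:4]; Rr <- y[5]
  Sm <- y[6]; Im <- y[7:9]; Rm <- y[10]
  dSr <- sum(-b * Sr * Ir) + p$mu * Rr - p$d * Sr
  dSm <- sum(-b * Sm * Im) + p$mu * Rm - p$d * Sm
  dIr <- b * Sr * Ir - p$nu1 * Ir - (p$d + p$alpha) * Ir
  dIm <- b * Sm * Im - p$nu2 * Im - (p$d + p$alpha) * Im
  dRr <- p$nu1 * sum(Ir) - p$mu * Rr - p$d * Rr
  dRm <- p$nu2 * sum(Im) - p$mu * Rm - p$d * Rm
  c(dSr, dIr, dRr, dSm, dIm, dRm)
}

rk4_integrate <- function(f, y, duration, p, h = 1e-4) {
  nstep <- round(duration / h)
  stopifnot(abs(nstep * h - duration) < 1e-12)
  for (k in seq_len(nstep)) {
    k1 <- f(y, p)
    k2 <- f(y + h / 2 * k1, p)
    k3 <- f(y + h / 2 * k2, p)
    k4 <- f(y + h * k3, p)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

oracle_pulse <- function(y, p) {
  y[6] <- (1 - p$delta_S) * y[6]
  y[7:9] <- (1 - p$delta_I) * y[7:9]
  y[10] <- (1 - p$delta_R) * y[10]
  y
}

oracle_one_year <- function(y, p, h = 1e-4) {
  y <- rk4_integrate(oracle_rhs_shared, y, p$T1, p, h)
  y <- oracle_pulse(y, p)
  y <- rk4_integrate(oracle_rhs_separate, y, p$T2, p, h)
  oracle_pulse(y, p)
}

# --- SIS variant: Sr, Ir1-3, Sm, Im1-3; recovery goes I -> S directly. ---

sis_rhs_shared <- function(t, y, p) {
  b <- oracle_beta(p)
  N <- sum(y)
  Sr <- y[1]; Ir <- y[2:4]; Sm <- y[5]; Im <- y[6:8]
  pool <- Ir + Im
  dSr <- -Sr * sum(b * pool) + p$nu1 * sum(Ir) +
    (p$b * Sr + (p$b + p$sigma) * sum(Ir)) * (1 - p$gamma * N) - p$d * Sr
  dSm <- -Sm * sum(b * pool) + p$nu1 * sum(Im) +
    (p$b * Sm + (p$b + p$sigma) * sum(Im)) * (1 - p$gamma * N) - p$d * Sm
  dIr <- b * Sr * pool - p$nu1 * Ir - (p$d + p$alpha) * Ir
  dIm <- b * Sm * pool - p$nu1 * Im - (p$d + p$alpha) * Im
  list(c(dSr, dIr, dSm, dIm))
}

sis_rhs_separate <- function(t, y, p) {
  b <- oracle_beta(p)
  Sr <- y[1]; Ir <- y[2:4]; Sm <- y[5]; Im <- y[6:8]
  dSr <- -Sr * sum(b * Ir) + p$nu1 * sum(Ir) - p$d * Sr
  dSm <- -Sm * sum(b * Im) + p$nu2 * sum(Im) - p$d * Sm
  dIr <- b * Sr * Ir - p$nu1 * Ir - (p$d + p$alpha) * Ir
  dIm <- b * Sm * Im - p$nu2 * Im - (p$d + p$alpha) * Im
  list(c(dSr, dIr, dSm, dIm))
}

run_sis_oracle <- function(p, years, y0 = rep(100, 8)) {
  y <- y0
  for (k in seq_len(years)) {
    y_prev <- y
    sol <- deSolve::ode(y, c(0, p$T1), sis_rhs_shared, p,
                        rtol = 1e-8, atol = 1e-10)
    y <- pmax(sol[nrow(sol), -1], 0)
    y[5] <- (1 - p$delta_S) * y[5]
    y[6:8] <- (1 - p$delta_I) * y[6:8]
    sol <- deSolve::ode(y, c(0, p$T2), sis_rhs_separate, p,
                        rtol = 1e-8, atol = 1e-10)
    y <- pmax(sol[nrow(sol), -1], 0)
    y[5] <- (1 - p$delta_S) * y[5]
    y[6:8] <- (1 - p$delta_I) * y[6:8]
    if (max(abs(y - y_prev)) / max(max(abs(y)), 1e-8) < 1e-10) break
  }
  y
}

sis_oracle_winner <- function(p, years, threshold = 1e-6) {
  y <- unname(run_sis_oracle(p, years))
  tot <- y[2:4] + y[6:8]
  if (max(tot) < threshold) NA_integer_ else which.max(tot)
}

# Random valid states for property tests (fixed seed set by callers).
random_state <- function(max = 500) {
  setNames(runif(10, 0, max), ORACLE_ORDER)
}

random_params <- function() {
  a1 <- runif(1, 0, 0.05)
  model_params(
    b = runif(1, 0.5, 3), d = runif(1, 0.05, 0.3),
    alpha = c(a1, a1 + runif(1, 0.01, 0.1), a1 + runif(1, 0.12, 0.3)),
    sigma = runif(1, -0.05, 0), gamma = 10^runif(1, -5, -3),
    delta_S = runif(1, 0, 0.01), delta_I = runif(1, 0, 0.05),
    delta_R = runif(1, 0, 0.01), mu = runif(1, 0, 1),
    nu1 = runif(1, 0, 0.5)
  )
}
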