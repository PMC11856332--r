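---
title: "Model and methods: multi-strain SIRS dynamics under partial migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: multi-strain SIRS dynamics under partial migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirsmig)
```

## The question

Seasonal migration changes the selective environment a pathogen lives in:
migrants pay a mortality toll each trip, but they also recover faster in
their second habitat ("migratory recovery"), and infected migrants may pay a
disproportionate toll ("migratory culling"). **sirsmig** asks which of three
pathogen strains — differing only in virulence, and linked to transmission
through a trade-off — ends up dominating a partially migratory host
population, and how that answer depends on how fast hosts recover, how fast
they lose immunity, and how costly migration is for infected hosts.

## The model

Hosts are split into residents and migrants, each with five compartments:
susceptible ($S$), infected with strain $i \in \{1,2,3\}$ ($I_i$), and
resistant ($R$) — ten classes in all, treated as continuous non-negative
densities. Strain $i$ kills infected hosts at virulence rate $\alpha_i$
(defaults $0.01, 0.05, 0.1$ per year) and transmits at rate
$\beta_i = \beta(\alpha_i)$.

One year has length 1 and is split into two seasons:

**Shared season (length $T_1 = 0.5$).** Both host types are in Habitat 1.
For residents (migrants are symmetric, with $m$ in place of $r$):

$$\frac{dS_r}{dt} = -S_r\sum_i \beta_i (I_{ri}+I_{mi}) + \mu R_r
 + \big[b\,(S_r+R_r) + (b+\sigma)\textstyle\sum_i I_{ri}\big](1-\gamma N) - d S_r$$

$$\frac{dI_{ri}}{dt} = \beta_i S_r (I_{ri}+I_{mi}) - \nu_1 I_{ri} - (d+\alpha_i) I_{ri},
\qquad
\frac{dR_r}{dt} = \nu_1 \sum_i I_{ri} - (\mu + d) R_r$$

Transmission pools infecteds of both host types; reproduction happens only
in this season, with the density-dependent factor $1-\gamma N$ ($N$ = all
ten classes) and a fecundity cost $\sigma$ (stored signed, $-0.02$, and
*added* to $b$) for infected parents. There is no coinfection, and host
type is fixed for life.

**Separate season (length $T_2 = 0.5$).** Migrants are in Habitat 2:
transmission is within host type only, there are no births, residents
recover at $\nu_1$ but migrants at $\nu_2 = \nu_1 + 0.12$ (migratory
recovery).

**Migration pulses.** At both season boundaries the migrant classes are
multiplied by $1-\delta_S$, $1-\delta_I$, $1-\delta_R$ ($S$, $I_i$, $R$
respectively); residents are untouched. The annual cycle is therefore:
integrate shared for $T_1$ → pulse → integrate separate for $T_2$ → pulse,
and simulations iterate this map for 2000 years from 100 individuals in
each class.

## The transmission–virulence trade-off

The biological requirement is that transmission rises with virulence with
diminishing returns (concave down). The default form used here is

$$\beta(\alpha) = c_A \sqrt{c_B + \alpha}, \qquad c_A = 0.005,\; c_B = 0.14,$$

which is strictly increasing and strictly concave on $\alpha \ge 0$ and
uses both constants: $c_A$ scales overall transmissibility and $c_B$ sets
the transmission a pathogen obtains before paying any mortality cost. Two
alternatives ship for sensitivity analysis, selectable via
`tradeoff_form`: a decreasing `"ratio"` form $c_A/(c_B+\alpha)$ and a
`"linear"` form $c_A c_B + \alpha$. The ratio form cannot produce a
high-virulence-wins region (transmission falls with virulence), and the
linear form is not concave; the qualitative phase-diagram results reported
by the package are therefore stated for the concave default, and the test
suite additionally runs — but does not assert on — the ratio variant.

A useful back-of-envelope: in a well-mixed season, strain $i$ persists down
to susceptible density $S^*_i = (\nu + d + \alpha_i)/\beta_i$, and the
strain with the smallest $S^*$ excludes the others. Under the default form
this predicts strain 1 to win for small $\nu_1$ and strain 3 for large
$\nu_1$, with switches near $\nu_1 \approx 0.17$ and $0.21$ — the full
seasonal model reproduces exactly this structure, shifted slightly by
migration costs and immunity loss.

## Outcomes

* **Winning strain** (`winning_strain()`): the strain whose pooled infected
  compartments (residents + migrants) are largest in the final state. Losing
  strains decay towards zero but never reach it in an ODE, so a strain with
  a pooled total below $10^{-6}$ individuals is treated as absent; if all
  are, the pathogen is extinct. The winner is invariant to rescaling the
  final state, so "largest proportion of the population" and "largest
  infected compartment" give the same answer. Exact ties (measure zero;
  flagged with a warning when within $10^{-9}$ relative) break towards the
  less virulent strain.
* **Host-strategy dominance** (`host_strategy_dominance()`): migrants
  dominate when their five classes outnumber the residents' five. Exact
  ties count as resident dominance, since any positive migration mortality
  strictly shrinks an otherwise symmetric migrant pool.

## Numerical choices

* **Integrator.** `deSolve::ode` (lsoda), relative tolerance $10^{-8}$,
  absolute tolerance $10^{-10}$, with the two seasonal fields implemented
  in C in the standard deSolve compiled-model style. The fields are smooth
  and non-stiff at the default scales; the pulses are handled outside the
  integrator, so no event detection is required. Exported pure-R copies of
  the fields (`rhs_shared_habitat()`, `rhs_separate_habitats()`) are the
  reference definition; the test suite holds the two implementations to
  term-by-term agreement at random states and checks a whole annual cycle
  against a fixed-step classical Runge–Kutta oracle (step $10^{-4}$) to
  $10^{-6}$ relative.
* **Clamping.** Round-off can push a compartment a hair below zero; values
  in $[-10^{-8}, 0)$ are clamped to zero at season boundaries, and anything
  below $-10^{-8}$ is escalated as a solver failure.
* **Horizon and early stopping.** The default horizon is 2000 years with
  no early stopping. `early_stop = TRUE` halts once consecutive end-of-year
  states agree to $10^{-10}$ relative — useful when only the converged
  pattern matters — and must stay off when the full-horizon trajectory
  itself is the object of interest. Near winner-transition boundaries
  competitive exclusion is slow and the criterion simply does not trigger,
  so early stopping never changes a converged answer.
* **Population ceiling.** Births shut off at $N = 1/\gamma = 10{,}000$; no
  other term adds individuals, so trajectories started below the ceiling
  stay below it (verified as an invariant test).

## Limiting cases

The SIRS structure nests the classic models, and the package exposes them
as named scenarios: `"SI"` ($\nu_1=\nu_2=0$: no recovery, the resistant
classes drain at rate $\mu+d$ and low virulence wins), `"SIR"` ($\mu=0$:
permanent immunity), and `"SIS"` (fast immunity loss). The true SIS limit
is $\mu \to \infty$; the scenario uses $\mu = 20$ per year (mean immune
residence 0.05 years, far below every other time scale) as a finite
stand-in, and the test suite checks that its winner map matches an
independently coded 8-compartment SIS variant in which recovery routes
infecteds straight back to susceptibility.

## Sweeps and boundaries

`phase_map()` grids $(\mu, \nu_1)$, rerunning the full competition in each
cell with $\nu_2 = \nu_1 + 0.12$ tied to the varied $\nu_1$; cells are
independent by construction. `transition_boundaries()` profiles, for each
$\mu$, the smallest $\nu_1$ at which the winner index first reaches 2 and
first reaches 3, by bisection to a $\nu_1$ tolerance of $10^{-3}$ after a
coarse monotonicity pre-scan (with a dense-scan fallback, logged, if the
winner were ever non-monotone along $\nu_1$). When two strains swap
directly (1 → 3), both thresholds coincide; when no switch occurs in range
the threshold is `NA`.

Axis ranges are package choices: $\mu \in [0, 1]$ (spanning the SIR edge
to fast immunity loss) and $\nu_1 \in [0, 0.5]$ (spanning the SI edge to
recovery fast enough that the most virulent strain wins everywhere), on a
6 × 6 reduced grid with $\delta_I \in \{1, 4, 8\} \times \delta_S$ for the
culling comparison. These grids are sized so that a full-horizon sweep
runs in about a minute and the three-level boundary comparison in a few
minutes on one core.

Two qualitative claims from the sweeps need operational definitions, fixed
here: "longer immune residence favours virulence" is checked as the winner
index being non-decreasing along $\nu_1$ at fixed $\mu$ and non-increasing
along $\mu$ at fixed $\nu_1$ (equivalently non-decreasing along the
lower-right → upper-left diagonal); and "migrants dominate only at low
immunity loss and high recovery" is checked as every migrant-dominant cell
lying in the lower half of the $\mu$ range, off the no-recovery edge, in a
cell won by strain 2 or 3 — the high-$\nu_1$ region — reflecting the
observation that migrant-favourable conditions coincide with wins by more
virulent strains.

## What the scenarios do and do not emulate

The named scenarios and grids reproduce the model's study conditions
exactly (parameter defaults, 100-per-class initial conditions, 2000-year
horizon, the varied-parameter values of the reference figures). They are
still a deterministic ODE world: no demographic stochasticity, no
in-transit infection during migration (migration is instantaneous), no
coinfection, no host evolution (migrant/resident identity is fixed), and
density dependence acts on fecundity only, not mortality. Passing tests
therefore certify the model's behaviour, not the behaviour of any real
host–pathogen system.

## Known limitations

* The winner near a transition boundary converges slowly (competitive
  exclusion is nearly neutral there), so boundary locations inherit a weak
  horizon dependence; the package always compares boundaries computed at
  the same horizon.
* $\mu = 20$ is a proxy for the SIS limit, not the limit itself; immune
  residence is short but positive, and the two migrant `R`/`S` pulse
  fractions differ slightly from a true SIS bookkeeping.
* The trade-off constants $c_A, c_B$ place the interesting structure in
  $\nu_1 \in [0, 0.5]$; other constants shift the transition locations,
  though not the orderings, which is what the package asserts on.
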