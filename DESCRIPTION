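Package: sirsmig
Title: Multi-Strain SIRS Dynamics in Partially Migratory Host Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a seasonally forced SIRS (susceptible-infected-
    resistant-susceptible) compartmental model in which a host population is
    split into residents and migrants and three pathogen strains of
    increasing virulence compete under a transmission-virulence trade-off.
    The annual cycle alternates a shared-habitat season (with reproduction
    and cross-type transmission) and a separate-habitat season (with
    habitat-dependent recovery), punctuated by pulsed migration mortality.
    Provides scenario constructors, deterministic multi-year simulation,
    outcome summaries (winning pathogen strain, migrant-versus-resident
    dominance), parameter sweeps producing phase maps over immunity-loss and
    recovery rates, bisection location of winner-transition boundaries,
    tidy() and glance() methods, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
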