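#' Construct a compartment state vector
#'
#' The model tracks 10 host classes: susceptible, strain-1/2/3 infected and
#' resistant residents (`Sr`, `Ir1`, `Ir2`, `Ir3`, `Rr`) and the same five
#' classes for migrants (`Sm`, `Im1`, `Im2`, `Im3`, `Rm`). Densities are
#' continuous and non-negative.
#'
#' @param Sr,Ir1,Ir2,Ir3,Rr,Sm,Im1,Im2,Im3,Rm Non-negative counts.
#' @return A named numeric vector of length 10 in canonical order.
#' @examples
#' state_vector(Sr = 100, Im2 = 50)
#' total_population(state_vector(Sr = 100, Im2 = 50))
#' @export
state_vector <- function(Sr = 0, Ir1 = 0, Ir2 = 0, Ir3 = 0, Rr = 0,
                         Sm = 0, Im1 = 0, Im2 = 0, Im3 = 0, Rm = 0) {
  as_state(c(Sr = Sr, Ir1 = Ir1, Ir2 = Ir2, Ir3 = Ir3, Rr = Rr,
             Sm = Sm, Im1 = Im1, Im2 = Im2, Im3 = Im3, Rm = Rm))
}

# Coerce/validate a named numeric vector into canonical compartment order.
as_state <- function(x) {
  if (!is.numeric(x) || is.null(names(x)) || !setequal(names(x), COMPARTMENTS))
    abort("a state needs exactly the 10 named compartments Sr..Rm",
          class = "sirsmig_invalid_state")
  x <- x[COMPARTMENTS]
  if (any(!is.finite(x)) || any(x < 0))
    abort("state compartments must be finite and non-negative",
          class = "sirsmig_invalid_state")
  x
}

#' Total host population size
#'
#' Sum of all 10 compartments, the `N` entering the density-dependent birth
#' factor `1 - gamma * N`.
#'
#' @param state A state vector from [state_vector()].
#' @return Total number of individuals.
#' @export
total_population <- function(state) sum(as_state(state))

# Per-strain infected totals, pooling residents and migrants.
strain_totals <- function(state) {
  state <- as_state(state)
  unname(state[c("Ir1", "Ir2", "Ir3")] + state[c("Im1", "Im2", "Im3")])
}
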