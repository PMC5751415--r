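# Physical constants used throughout; kcal/mol, Angstrom, e, K units.

#' Physical constants
#'
#' Constants used by the thermodynamic and electrostatic routines:
#' the gas constant in kcal mol^-1 K^-1 and the Coulomb constant in
#' kcal A mol^-1 e^-2.
#'
#' @format A named list with elements `R_gas` (1.9872e-3) and
#'   `k_coulomb` (332.0636).
#' @export
cgbsa_constants <- list(
  R_gas = 1.9872e-3,      # kcal mol^-1 K^-1
  k_coulomb = 332.0636    # kcal A mol^-1 e^-2
)

# Debye screening length for water near 300 K: lambda_D = 0.304/sqrt(I) nm.
# Returns kappa in A^-1; zero ionic strength gives zero screening.
debye_kappa <- function(salt_conc) {
  if (salt_conc <= 0) return(0)
  sqrt(salt_conc) / 3.04
}
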