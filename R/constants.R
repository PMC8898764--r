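#' Physical constants used throughout hdespin
#'
#' All internal energies are in wavenumbers (cm^-1), temperatures in kelvin,
#' magnetic fields in tesla, molar susceptibility-temperature products
#' (chi*T) in cm^3 K mol^-1 and magnetic moments in Bohr magnetons per
#' molecule.
#'
#' @format A named list with components:
#' \describe{
#'   \item{kB_cm}{Boltzmann constant, 0.6950348 cm^-1 K^-1.}
#'   \item{muB_cm_per_T}{Bohr magneton, 0.46686 cm^-1 T^-1.}
#'   \item{curie_C}{N_A mu_B^2 / (3 k_B) = 0.125049 cm^3 K mol^-1, the
#'     prefactor of the Curie law chi*T = C g^2 S(S+1).}
#'   \item{g_e}{Free-electron g value, 2.0023.}
#' }
#' @export
hdespin_constants <- list(
  kB_cm        = 0.6950348,
  muB_cm_per_T = 0.46686,
  curie_C      = 0.125049,
  g_e          = 2.0023
)

.kB  <- hdespin_constants$kB_cm
.muB <- hdespin_constants$muB_cm_per_T
.C0  <- hdespin_constants$curie_C

# half-integer/integer check with floating-point slack
.is_half_integral <- function(x, tol = 1e-9) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 &&
    abs(2 * x - round(2 * x)) < tol
}
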