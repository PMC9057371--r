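## Physical constants (SI).  These are the only SI numbers in the package:
## everything downstream works in reduced units (lengths nm, energies kT,
## charges e).
.const <- list(
  e  = 1.602176634e-19,   # elementary charge, C
  kB = 1.380649e-23,      # Boltzmann constant, J/K
  eps0 = 8.8541878128e-12, # vacuum permittivity, F/m
  N_A = 6.02214076e23     # Avogadro number, 1/mol
)

#' Convert a molar concentration to a number density
#'
#' @param c Concentration in mol/L.
#' @return Number density in nm^-3.
#' @export
molar_to_number_density <- function(c) {
  if (any(c < 0)) stop("concentration must be non-negative")
  c * .const$N_A * 1e-24
}

#' Bjerrum length of a dielectric continuum
#'
#' The distance at which two elementary charges interact with thermal energy
#' kT: lambda_B = e^2 / (4 pi eps0 eps kB T).
#'
#' @param eps Relative dielectric constant (dimensionless).
#' @param temperature Absolute temperature in K.
#' @return Bjerrum length in nm.
#' @export
bjerrum_length <- function(eps, temperature) {
  if (eps <= 0 || temperature <= 0) stop("eps and temperature must be positive")
  1e9 * .const$e^2 / (4 * pi * .const$eps0 * eps * .const$kB * temperature)
}

#' Macroion valence from surface charge density
#'
#' Inverts Q = Z_M e / (4 pi R^2): the total charge spread uniformly over the
#' sphere surface.
#'
#' @param Q Surface charge density in C/m^2.
#' @param R Macroion radius in nm.
#' @return Valence Z_M in units of e (signed, not rounded).
#' @export
macroion_valence <- function(Q, R) {
  if (any(R <= 0)) stop("R must be positive")
  4 * pi * (R * 1e-9)^2 * Q / .const$e
}

#' Surface charge density from macroion valence (inverse of
#' \code{\link{macroion_valence}})
#'
#' @param Z_M Macroion valence in e.
#' @param R Macroion radius in nm.
#' @return Surface charge density in C/m^2.
#' @export
surface_charge_density <- function(Z_M, R) {
  if (any(R <= 0)) stop("R must be positive")
  Z_M * .const$e / (4 * pi * (R * 1e-9)^2)
}
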