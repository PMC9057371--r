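#' Define an electrolyte or solvent species
#'
#' A species is a charged or neutral hard sphere: the solvent primitive model
#' treats the solvent exactly like an ion with valence zero.
#'
#' @param label Species name (e.g. "Mg", "Na", "Cl", "solvent").
#' @param diameter Hard-sphere diameter sigma in nm.
#' @param valence Integer charge z in units of e (0 for the solvent).
#' @param concentration Bulk concentration in mol/L.
#' @return An object of class \code{sdl_species}.
#' @export
species <- function(label, diameter, valence, concentration) {
  if (diameter <= 0) stop("diameter must be positive")
  if (concentration < 0) stop("concentration must be non-negative")
  if (valence != round(valence)) stop("valence must be integer-valued")
  structure(list(label = as.character(label), diameter = diameter,
                 valence = as.integer(valence), concentration = concentration,
                 density = molar_to_number_density(concentration)),
            class = "sdl_species")
}

#' Define the central macroion
#'
#' Either the valence \code{Z_M} or the surface charge density \code{Q} may be
#' given; the other is filled in through Q = Z_M e/(4 pi R^2).  If both are
#' given they must agree to 1e-6 relative.
#'
#' @param radius Macroion radius R in nm.
#' @param Z_M Valence in e (optional).
#' @param Q Surface charge density in C/m^2 (optional).
#' @return An object of class \code{sdl_macroion}.
#' @export
macroion <- function(radius, Z_M = NULL, Q = NULL) {
  if (radius <= 0) stop("radius must be positive")
  if (is.null(Z_M) && is.null(Q)) stop("give Z_M or Q")
  if (is.null(Z_M)) Z_M <- macroion_valence(Q, radius)
  if (is.null(Q))  Q  <- surface_charge_density(Z_M, radius)
  Zq <- macroion_valence(Q, radius)
  scale <- max(abs(Z_M), abs(Zq), 1e-12)
  if (abs(Z_M - Zq) > 1e-6 * scale)
    stop("inconsistent Z_M and Q: Q = Z_M e/(4 pi R^2) violated beyond 1e-6 relative")
  structure(list(radius = radius, valence = Z_M, surface_charge_density = Q),
            class = "sdl_macroion")
}

#' Assemble a full system specification
#'
#' The single source of physical truth for all solvers: the species set, the
#' macroion, the dielectric constant of the continuum and the temperature.
#'
#' @param species_list List of \code{\link{species}} objects.
#' @param macroion A \code{\link{macroion}} object.
#' @param eps Relative dielectric constant.
#' @param temperature Temperature in K.
#' @param check If TRUE (default), run \code{\link{validate_system}}.
#' @return An object of class \code{sdl_system}.
#' @export
system_spec <- function(species_list, macroion, eps = 78.5, temperature = 298,
                        check = TRUE) {
  if (inherits(species_list, "sdl_species")) species_list <- list(species_list)
  stopifnot(length(species_list) >= 1, inherits(macroion, "sdl_macroion"))
  if (eps <= 0 || temperature <= 0) stop("eps and temperature must be positive")
  s <- structure(list(
    species = species_list,
    macroion = macroion,
    eps = eps,
    temperature = temperature,
    lambda_B = bjerrum_length(eps, temperature)
  ), class = "sdl_system")
  if (check) validate_system(s, quiet = TRUE)
  s
}

## vector accessors used throughout the solvers
sp_sigma   <- function(spec) vapply(spec$species, `[[`, numeric(1), "diameter")
sp_valence <- function(spec) vapply(spec$species, `[[`, numeric(1), "valence")
sp_density <- function(spec) vapply(spec$species, `[[`, numeric(1), "density")
sp_label   <- function(spec) vapply(spec$species, `[[`, character(1), "label")

#' Validate a system specification
#'
#' Checks bulk electroneutrality, packing fractions, and that at most one
#' species is a neutral solvent; reports the Debye length and macroion valence.
#'
#' @param spec An \code{sdl_system}.
#' @param quiet If TRUE, suppress the printed report.
#' @return (Invisibly) a list with kappa, debye_length_nm, packing fractions
#'   and Z_M.
#' @export
validate_system <- function(spec, quiet = FALSE) {
  sig <- sp_sigma(spec); z <- sp_valence(spec); rho <- sp_density(spec)
  if (sum(z == 0 & rho > 0) > 1)
    stop("at most one species may be a neutral solvent")
  qsum <- sum(z * rho)
  qscale <- sum(abs(z) * rho)
  if (qscale > 0 && abs(qsum) > 1e-9 * qscale)
    stop("bulk electroneutrality violated: sum z_a rho_a = ", signif(qsum, 4),
         " nm^-3")
  eta <- pi / 6 * rho * sig^3
  if (sum(eta) >= 0.74)
    stop("total packing fraction ", signif(sum(eta), 4), " >= 0.74")
  kap <- sqrt(4 * pi * spec$lambda_B * sum(rho * z^2))
  rep <- list(kappa = kap,
              debye_length_nm = if (kap > 0) 1 / kap else Inf,
              packing_fractions = stats::setNames(eta, sp_label(spec)),
              total_packing = sum(eta),
              Z_M = spec$macroion$valence)
  if (!quiet) {
    cat("system valid:\n")
    cat(sprintf("  Z_M = %.4g e, kappa = %.4g 1/nm (Debye length %.4g nm)\n",
                rep$Z_M, rep$kappa, rep$debye_length_nm))
    cat(sprintf("  packing fractions: %s (total %.4g)\n",
                paste(sprintf("%s %.4g", names(rep$packing_fractions),
                              rep$packing_fractions), collapse = ", "),
                rep$total_packing))
  }
  invisible(rep)
}

#' Pair interaction between two species
#'
#' Hard-sphere plus Coulomb in reduced units: +Inf inside contact, otherwise
#' lambda_B z_a z_b / r (kT).  Neutral pairs reduce to pure hard spheres.
#'
#' @param a,b \code{sdl_species} objects.
#' @param r Center-to-center distance(s) in nm.
#' @param spec An \code{sdl_system} supplying lambda_B (eps, T).
#' @return Energy in kT (vectorized over r).
#' @export
pair_potential <- function(a, b, r, spec) {
  if (any(r <= 0)) stop("r must be positive")
  contact <- (a$diameter + b$diameter) / 2
  u <- spec$lambda_B * a$valence * b$valence / r
  u[r < contact] <- Inf
  u
}

#' Interaction between a species and the macroion
#'
#' +Inf for r < R + sigma_a/2 (hard wall at the species' distance of closest
#' approach), otherwise lambda_B Z_M z_a / r.  The solvent (z=0) sees only the
#' hard wall.
#'
#' @param a An \code{sdl_species}.
#' @param M An \code{sdl_macroion}.
#' @param r Distance(s) from the macroion center in nm.
#' @param spec An \code{sdl_system} supplying lambda_B.
#' @return Energy in kT (vectorized over r).
#' @export
macroion_potential <- function(a, M, r, spec) {
  if (any(r <= 0)) stop("r must be positive")
  u <- spec$lambda_B * M$valence * a$valence / r
  u[r < M$radius + a$diameter / 2] <- Inf
  u
}

#' @export
print.sdl_system <- function(x, ...) {
  cat("solvent-primitive-model system\n")
  cat(sprintf("  macroion: R = %g nm, Z_M = %.4g e (Q = %.4g C/m^2)\n",
              x$macroion$radius, x$macroion$valence,
              x$macroion$surface_charge_density))
  for (s in x$species)
    cat(sprintf("  %-8s sigma = %g nm, z = %+d, c = %g M\n",
                s$label, s$diameter, s$valence, s$concentration))
  cat(sprintf("  eps = %g, T = %g K, lambda_B = %.4g nm\n",
              x$eps, x$temperature, x$lambda_B))
  invisible(x)
}
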