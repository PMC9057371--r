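## Derived double-layer observables: integrated charge P(r), charge-reversal
## and amplification diagnostics, and the capacitive compactness tau_c.

#' Integrated charge distribution function P(r)
#'
#' P(r) = Z_M + 4 pi sum_a z_a int_R^r s^2 rho_a(s) ds: the net charge (in e)
#' enclosed within radius r, macroion included, so that P(R) = Z_M and
#' P(infinity) = 0 by electroneutrality.
#'
#' @param profiles An \code{sdl_profiles} (or list with grid, rho).
#' @param spec The system.
#' @return Vector of P values (e) at the grid nodes.
#' @export
integrated_charge <- function(profiles, spec) {
  r <- profiles$grid$r
  z <- sp_valence(spec)
  q <- as.numeric(profiles$rho %*% z)
  spec$macroion$valence + 4 * pi * .cumtrapz(r, r^2 * q)
}

#' Ionic-only integrated charge (without the macroion term)
#'
#' @inheritParams integrated_charge
#' @return Vector of cumulative ionic charge (e).
#' @export
integrated_ionic_charge <- function(profiles, spec) {
  integrated_charge(profiles, spec) - spec$macroion$valence
}

#' Classify the charge state of a double layer
#'
#' Charge reversal (CR): the enclosed charge P(r) changes sign relative to
#' the bare macroion, P(r) Z_M < 0.  Surface charge amplification: |P(r)|
#' exceeds |Z_M| with unchanged sign.  The adsorbed charge amplification is
#' Delta Z_M = max_r P(r) - Z_M (for Z_M > 0; mirrored for Z_M < 0).
#'
#' @param P Integrated charge on the grid (from
#'   \code{\link{integrated_charge}}).
#' @param r Grid nodes.
#' @param Z_M Bare macroion valence.
#' @return List with \code{cr} flag and \code{cr_radius} (first sign
#'   crossing, NA if none), \code{amplification} flag and
#'   \code{amp_radius} (location of max |P|), and \code{delta_Z}.
#' @export
classify_charge_state <- function(P, r, Z_M) {
  if (Z_M == 0)
    return(list(cr = NA, cr_radius = NA_real_, amplification = NA,
                amp_radius = NA_real_, delta_Z = NA_real_))
  s <- sign(Z_M)
  crm <- which(P * Z_M < 0)
  cr <- length(crm) > 0
  cr_radius <- if (cr) {
    k <- crm[1]
    if (k > 1) {  # linear interpolation of the first zero crossing
      r[k - 1] + (r[k] - r[k - 1]) * P[k - 1] / (P[k - 1] - P[k])
    } else r[k]
  } else NA_real_
  ampm <- which(abs(P) > abs(Z_M) & P * Z_M > 0)
  amplification <- length(ampm) > 0
  amp_radius <- if (amplification) r[ampm[which.max(abs(P[ampm]))]] else NA_real_
  delta_Z <- s * (max(s * P) - s * Z_M)
  list(cr = cr, cr_radius = cr_radius, amplification = amplification,
       amp_radius = amp_radius, delta_Z = delta_Z)
}

#' Capacitive compactness of the double layer
#'
#' The radius tau_c of the concentric shell that, carrying the full
#' countercharge -Z_M, would reproduce the surface potential psi_0 as an
#' ideal spherical capacitor:
#'   beta e psi_0 = lam Z_M (1/R - 1/tau_c)  =>
#'   1/tau_c = 1/R - beta e psi_0 / (lam Z_M).
#' A compact double layer has tau_c close to R.
#'
#' @param psi0 Surface potential psi(R) in kT/e.
#' @param Z_M Macroion valence (nonzero).
#' @param R Macroion radius in nm.
#' @param spec The system (for lambda_B).
#' @return tau_c in nm; +Inf (with a warning) if psi0 implies no screening.
#' @export
capacitive_compactness <- function(psi0, Z_M, R, spec) {
  if (Z_M == 0) stop("tau_c undefined for an uncharged macroion")
  inv <- 1 / R - psi0 / (spec$lambda_B * Z_M)
  if (inv <= 0) {
    warning("surface potential at or above the bare-Coulomb value: ",
            "no screening, tau_c = Inf")
    return(Inf)
  }
  1 / inv
}

#' Full observable set of a converged/equilibrated profile set
#'
#' @param profiles An \code{sdl_profiles}.
#' @param spec The system.
#' @param psi0_at "surface" (default; psi evaluated at r = R) or "contact"
#'   (r = R + sigma_min/2).
#' @return An object of class \code{sdl_observables}: P(r), psi0, tau_c,
#'   delta_Z, CR/amplification flags and radii.
#' @export
observable_set <- function(profiles, spec, psi0_at = c("surface", "contact")) {
  psi0_at <- match.arg(psi0_at)
  r <- profiles$grid$r
  P <- integrated_charge(profiles, spec)
  ZM <- spec$macroion$valence
  r0 <- if (psi0_at == "surface") profiles$grid$R else
    profiles$grid$R + min(sp_sigma(spec)) / 2
  psi0 <- stats::approx(r, profiles$psi, xout = r0, rule = 2)$y
  cls <- classify_charge_state(P, r, ZM)
  tau <- if (ZM != 0) capacitive_compactness(psi0, ZM, profiles$grid$R, spec)
         else NA_real_
  structure(c(list(r = r, P = P, psi0 = psi0, tau_c = tau, Z_M = ZM), cls),
            class = "sdl_observables")
}

#' @export
print.sdl_observables <- function(x, ...) {
  cat(sprintf("Z_M = %.4g e, psi0 = %.5g kT/e, tau_c = %.5g nm\n",
              x$Z_M, x$psi0, x$tau_c))
  cat(sprintf("P(rmax) = %.4g e; CR: %s%s; amplification: %s; delta_Z = %.4g e\n",
              x$P[length(x$P)], x$cr,
              if (isTRUE(x$cr)) sprintf(" (first at %.4g nm)", x$cr_radius) else "",
              x$amplification, x$delta_Z))
  invisible(x)
}
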