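## Unequal-radius modified Gouy-Chapman reference: nonlinear
## Poisson-Boltzmann for point ions with species-specific distances of
## closest approach (Stern shells).  The solvent plays no role here beyond
## the dielectric continuum.

#' Solve the URMGC (nonlinear PB) equations
#'
#' Solves, with u = r psi (psi in kT/e),
#'   u'' = -4 pi lam r sum_a z_a rho0_a exp(-z_a u/r) theta(r - R - sigma_a/2)
#' subject to psi'(R) = -lam Z_M / R^2 and psi(rmax) = 0, by damped Newton
#' iteration on the finite-difference system (automatic fallback to a damped
#' Picard sweep if Newton fails to reduce the residual).
#'
#' @param spec Validated \code{sdl_system}; ionic species only enter (the
#'   neutral solvent is ignored).
#' @param grid Optional \code{sdl_grid}; default step min(sigma)/50, extent
#'   max(12/kappa, 4 sigma_max) beyond the surface.
#' @param controls List: \code{tol} (residual infinity-norm, 1e-10),
#'   \code{max_iter} (200).
#' @return Object of class \code{sdl_profiles} with \code{model = "urmgc"}:
#'   psi, Boltzmann densities (zero inside each Stern shell), psi0 = psi(R).
#' @export
solve_urmgc <- function(spec, grid = NULL, controls = list()) {
  ctl <- utils::modifyList(list(tol = 1e-10, max_iter = 200), controls)
  validate_system(spec, quiet = TRUE)
  sig <- sp_sigma(spec); z <- sp_valence(spec); rho_b <- sp_density(spec)
  ion <- z != 0 & rho_b > 0
  lam <- spec$lambda_B
  R <- spec$macroion$radius; ZM <- spec$macroion$valence
  kap <- debye_kappa(spec)
  if (is.null(grid)) {
    h <- min(sig[rho_b > 0]) / 50
    rmax <- R + max(if (kap > 0) 18 / kap else 4, 4 * max(sig))
    grid <- radial_grid(R, rmax, h)
  }
  r <- grid$r; h <- grid$h; n <- grid$n
  contact <- R + sig / 2
  ## indicator of the accessible region; a node sitting exactly on a contact
  ## radius carries weight 1/2 (midpoint value of the density step), which
  ## keeps the finite-difference source and all charge integrals O(h^2)
  live <- sapply(seq_along(z), function(a) {
    v <- as.numeric(r >= contact[a] - 1e-9)
    on <- abs(r - contact[a]) < 1e-9
    v[on] <- 0.5
    v
  })
  qfun <- function(psi) {   # charge density and its psi-derivative
    e <- exp(pmax(pmin(-outer(psi, z), 60), -60)) * live
    list(q = as.numeric((e * matrix(rho_b, n, length(z), byrow = TRUE)) %*% z),
         dq = -as.numeric((e * matrix(rho_b, n, length(z), byrow = TRUE)) %*% z^2))
  }
  ## residual F(u) and tridiagonal Jacobian bands (sub, diag, super)
  Fjac <- function(u) {
    psi <- u / r
    qq <- qfun(psi)
    Fv <- numeric(n); dl <- numeric(n - 1); dd <- numeric(n); du <- numeric(n - 1)
    ## Neumann at the surface (second-order one-sided):
    ## (-3u1 + 4u2 - u3)/(2h) - u1/R = -lam Z_M / R
    Fv[1] <- (-3 * u[1] + 4 * u[2] - u[3]) / (2 * h) - u[1] / R + lam * ZM / R
    dd[1] <- -3 / (2 * h) - 1 / R; du[1] <- 4 / (2 * h)
    extra13 <- -1 / (2 * h)       # coupling of row 1 to u[3]
    i <- 2:(n - 1)
    Fv[i] <- (u[i - 1] - 2 * u[i] + u[i + 1]) / h^2 +
      4 * pi * lam * r[i] * qq$q[i]
    dl[i - 1] <- 1 / h^2
    dd[i] <- -2 / h^2 + 4 * pi * lam * qq$dq[i]
    du[i] <- 1 / h^2
    Fv[n] <- u[n]
    dd[n] <- 1
    dl[n - 1] <- 0
    list(F = Fv, dl = dl, dd = dd, du = du, extra13 = extra13)
  }
  ## tridiagonal solve with the single extra (1,3) entry eliminated first
  tsolve <- function(j, b) {
    dl <- j$dl; dd <- j$dd; du <- j$du; x13 <- j$extra13
    n <- length(dd)
    ## eliminate the (1,3) entry using row 2
    f <- x13 / du[2]
    dd[1] <- dd[1] - f * dl[1]
    du[1] <- du[1] - f * dd[2]
    b[1] <- b[1] - f * b[2]
    ## Thomas algorithm
    for (i in 2:n) {
      m <- dl[i - 1] / dd[i - 1]
      dd[i] <- dd[i] - m * du[i - 1]
      b[i] <- b[i] - m * b[i - 1]
    }
    x <- numeric(n)
    x[n] <- b[n] / dd[n]
    for (i in (n - 1):1) x[i] <- (b[i] - du[i] * x[i + 1]) / dd[i]
    x
  }
  ## initial guess: DH with closest approach at the smallest Stern shell
  a0 <- min(contact[ion])
  psi_init <- if (kap > 0) lam * ZM * exp(-kap * pmax(r - a0, 0)) /
                 (r * (1 + kap * a0)) else lam * ZM / r - lam * ZM / r[n]
  u <- r * psi_init
  j <- Fjac(u); fn <- max(abs(j$F))
  newton_ok <- TRUE
  for (it in seq_len(ctl$max_iter)) {
    if (fn < ctl$tol) break
    duv <- tsolve(j, -j$F)
    step <- 1; improved <- FALSE
    for (ls in 1:30) {
      u_try <- u + step * duv
      j_try <- Fjac(u_try)
      fn_try <- max(abs(j_try$F))
      if (is.finite(fn_try) && fn_try < fn) {
        u <- u_try; j <- j_try; fn <- fn_try; improved <- TRUE; break
      }
      step <- step / 2
    }
    if (!improved) { newton_ok <- FALSE; break }
  }
  if (fn >= ctl$tol && !newton_ok) {
    ## damped Picard fallback: relax psi towards the Yukawa-solved field
    warning("URMGC Newton stalled at residual ", signif(fn, 3),
            "; switching to damped Picard")
    for (it in seq_len(5000)) {
      j <- Fjac(u); fn <- max(abs(j$F))
      if (fn < ctl$tol) break
      jl <- j; jl$dd[2:(n - 1)] <- -2 / h^2   # frozen (linear) operator
      u <- u + 0.5 * tsolve(jl, -j$F)
    }
  }
  if (fn >= ctl$tol * 10)
    warning("URMGC solver residual ", signif(fn, 3), " above tolerance")
  psi <- u / r
  rho <- sapply(seq_along(z), function(a)
    rho_b[a] * exp(pmax(pmin(-z[a] * psi, 60), -60)) * live[, a])
  rho[, !ion] <- 0
  structure(list(grid = grid, rho = rho, psi = psi, psi0 = psi[1],
                 converged = fn < ctl$tol * 10, residual = fn,
                 spec = spec, model = "urmgc"),
            class = "sdl_profiles")
}

#' Debye-Hueckel potential around a charged sphere
#'
#' Linearized screened potential with a common distance of closest approach a:
#'   beta e psi(r) = Z_M lam exp(-kappa (r - a)) / (r (1 + kappa a)).
#'
#' @param Z_M Macroion valence (e).
#' @param a Distance of closest approach in nm.
#' @param r Radii (nm), r >= a.
#' @param spec The system (lambda_B and kappa are taken from it).
#' @return psi in kT/e.
#' @export
dh_potential <- function(Z_M, a, r, spec) {
  kap <- debye_kappa(spec)
  Z_M * spec$lambda_B * exp(-kap * (r - a)) / (r * (1 + kap * a))
}
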