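## Picard solver for the density-functional equations of the spherical double
## layer: density equation (Boltzmann form with hard-sphere WDA and
## perturbative electrostatic one-particle DCF differences), mean
## electrostatic potential from the Gauss-law quadrature, iterated to a fixed
## point on a uniform radial grid.

#' Mean electrostatic potential from density profiles
#'
#' Two-term Gauss-law form, robust also before electroneutrality is reached:
#'   beta e psi(r) = lam Z_M / r
#'     + 4 pi lam [ (1/r) int_R^r s^2 q(s) ds + int_r^rmax s q(s) ds ],
#' q(s) = sum_a z_a rho_a(s), shifted so that psi(rmax) = 0.
#'
#' @param profiles List with \code{grid} and \code{rho} (nodes x species).
#' @param spec The system.
#' @return Vector of psi values in kT/e at the grid nodes.
#' @export
mep_from_profiles <- function(profiles, spec) {
  grid <- profiles$grid
  z <- sp_valence(spec); lam <- spec$lambda_B
  r <- grid$r
  q <- as.numeric(profiles$rho %*% z)
  I1 <- .cumtrapz(r, r^2 * q)
  I2c <- .cumtrapz(r, r * q)
  I2 <- I2c[length(I2c)] - I2c
  psi <- lam * spec$macroion$valence / r + 4 * pi * lam * (I1 / r + I2)
  psi - psi[length(psi)]
}

## stacked convolution operator for the short-range residual electrostatic
## kernels K_ab(s) = c_el,ab(s) + lam z_a z_b / s (compact support inside the
## cores; the mean-field 1/s tail is carried by the MEP term).
.build_el_operator <- function(spec, params, r_out, r_in) {
  rho <- sp_density(spec); sig <- sp_sigma(spec); z <- sp_valence(spec)
  lam <- spec$lambda_B
  ns <- length(rho); h <- r_in[2] - r_in[1]
  no <- length(r_out); ni <- length(r_in)
  M <- matrix(0, ns * no, ns * ni)
  if (params$gamma == 0) return(M)
  for (a in seq_len(ns)) for (b in a:ns) {
    reach <- (sig[a] + sig[b]) / 2
    Kf <- function(s) {
      v <- msa_el_dcf(params, spec, a, b, s)
      add <- numeric(length(s))
      pos <- s > 0 & s < reach
      add[pos] <- lam * z[a] * z[b] / s[pos]
      out <- v + add
      out[s >= reach] <- 0
      out
    }
    if (z[a] == 0 && z[b] == 0 && params$gamma == 0) next
    ci <- .kernel_cumint(Kf, reach, h)
    W <- .conv_operator(r_out, r_in, h, ci)
    M[(a - 1) * no + seq_len(no), (b - 1) * ni + seq_len(ni)] <- W
    if (b != a)
      M[(b - 1) * no + seq_len(no), (a - 1) * ni + seq_len(ni)] <- W
  }
  M
}

#' Perturbative electrostatic one-particle DCF profile
#'
#' The Eq.-8 difference c1_el,a(r) - c1_el,a(bulk) as the convolution of the
#' density deviations from bulk with the short-range residual MSA kernels.
#' Vanishes identically for uniform profiles.
#'
#' @param profiles List with \code{grid} and \code{rho}.
#' @param spec The system.
#' @param params MSA parameters (from \code{\link{solve_msa_gamma}}).
#' @return Matrix (nodes x species).
#' @export
c1_el_profile <- function(profiles, spec, params = solve_msa_gamma(spec)) {
  grid <- profiles$grid
  rho_b <- sp_density(spec); ns <- length(rho_b)
  ext <- .extend_profiles(profiles$rho, grid, spec)
  drho <- ext$rho - matrix(rho_b, nrow(ext$rho), ns, byrow = TRUE)
  ## below the surface and inside the exclusion zones the deviation is -rho0;
  ## .extend_profiles already encodes rho = 0 there and bulk beyond rmax.
  M <- .build_el_operator(spec, params, grid$r, ext$r)
  matrix(as.numeric(M %*% as.numeric(drho)), ncol = ns)
}

#' Solve the density functional theory of the spherical double layer
#'
#' Picard fixed-point iteration with adaptive mixing.  Initialization is the
#' Boltzmann profile in the bare Debye-Hueckel potential of the macroion.
#'
#' @param spec Validated \code{sdl_system}.
#' @param grid Optional \code{sdl_grid}; defaults to step sigma_min/40 and
#'   extent max(10/kappa, 8 sigma_max) beyond the surface.
#' @param controls List; recognised entries \code{mixing} (initial, 0.05),
#'   \code{tol} (1e-7), \code{max_iter} (5e4), \code{wda_mode}
#'   ("bulk_weights"), \code{verbose}.
#' @return An object of class \code{sdl_profiles}: grid, rho (nodes x
#'   species), psi (kT/e), converged flag, residual history, and the
#'   system/controls used.
#' @export
solve_dft <- function(spec, grid = NULL, controls = list()) {
  ctl <- utils::modifyList(list(mixing = 0.05, tol = 1e-7, max_iter = 5e4,
                                wda_mode = "bulk_weights", clip = 1,
                                mix_max = 0.2, anderson = 5, warmup = 80,
                                verbose = FALSE),
                           controls)
  validate_system(spec, quiet = TRUE)
  if (is.null(grid)) grid <- default_grid(spec)
  rho_b <- sp_density(spec); sig <- sp_sigma(spec); z <- sp_valence(spec)
  lam <- spec$lambda_B; ns <- length(rho_b)
  R <- spec$macroion$radius; ZM <- spec$macroion$valence
  r <- grid$r
  contact <- R + sig / 2
  alive <- sapply(seq_len(ns), function(a) r >= contact[a] - 1e-12)  # nodes x ns
  kap <- debye_kappa(spec)
  ## initial guess: Boltzmann in the linearized (DH) macroion potential
  aDH <- R
  psi0 <- if (kap > 0) lam * ZM * exp(-kap * (r - aDH)) / (r * (1 + kap * aDH))
          else lam * ZM / r - lam * ZM / grid$rmax
  rho <- sapply(seq_len(ns), function(a)
    rho_b[a] * exp(pmax(pmin(-z[a] * psi0, 30), -30)))
  rho <- rho * alive
  ## precompute operators
  params <- solve_msa_gamma(spec)
  ext0 <- .extend_profiles(rho, grid, spec)
  Mw <- .build_wda_operator(spec, r, ext0$r)
  Me <- .build_el_operator(spec, params, r, ext0$r)
  c1b <- uniform_c1_hs(rho_b, sig)
  mix <- ctl$mixing
  res_hist <- numeric(0)
  best <- Inf; worse_run <- 0; stable_run <- 0
  converged <- FALSE
  ## Anderson-stabilized mixing history (secant pairs on the stacked
  ## density vector); plain Picard during the warmup phase
  aa_m <- ctl$anderson
  aaX <- NULL; aaF <- NULL; x_prev <- NULL; f_prev <- NULL
  aa_beta <- NA_real_   # set at first engagement
  rho_best <- rho; resid_best <- Inf
  for (it in seq_len(ctl$max_iter)) {
    ext <- .extend_profiles(rho, grid, spec)
    rhobar <- .wda_apply(Mw, ext$rho, grid$n, ns)
    dc1hs <- matrix(0, length(r), ns)
    for (a in seq_len(ns))
      dc1hs[, a] <- .c1_hs_field(matrix(rhobar[, a, ], length(r), ns),
                                 sig)[, a] - c1b[a]
    drho_ext <- ext$rho - matrix(rho_b, nrow(ext$rho), ns, byrow = TRUE)
    dc1el <- matrix(as.numeric(Me %*% as.numeric(drho_ext)), ncol = ns)
    psi <- mep_from_profiles(list(grid = grid, rho = rho), spec)
    arg <- -outer(psi, z) + dc1hs + dc1el
    rhs <- matrix(rho_b, length(r), ns, byrow = TRUE) *
      exp(pmax(pmin(arg, 40), -60))
    rhs <- rhs * alive
    ## trust-region clip: bound the per-iteration logarithmic change (the
    ## fixed point is untouched; this only tames the transient at high
    ## packing).  Inactive wherever rho is still zero/hard-excluded.
    up <- exp(ctl$clip); lo <- exp(-ctl$clip)
    pos <- rho > 0
    rhs[pos] <- pmin(pmax(rhs[pos], rho[pos] * lo), rho[pos] * up)
    resid <- max(abs(rhs - rho) %*% diag(1 / pmax(rho_b, 1e-300), ns))
    res_hist <- c(res_hist, resid)
    if (resid < ctl$tol) { rho <- rhs; converged <- TRUE; break }
    if (resid < resid_best) { resid_best <- resid; rho_best <- rho }
    if (resid < best) { best <- resid; worse_run <- 0 } else
      worse_run <- worse_run + 1
    stable_run <- stable_run + 1
    ## runaway: return to the best iterate with a more cautious update
    if (resid > 1e3 * resid_best || !all(is.finite(rhs))) {
      rho <- rho_best; aaX <- aaF <- NULL; x_prev <- f_prev <- NULL
      mix <- max(mix / 4, 1e-4)
      aa_beta <- if (is.na(aa_beta)) NA_real_ else max(aa_beta / 2, 0.01)
      best <- Inf; worse_run <- 0; stable_run <- 0
      next
    }
    if (worse_run >= 50 && aa_m == 0)
      stop("DFT Picard iteration diverging; try a smaller mixing parameter ",
           "(current ", signif(mix, 3), ")")
    if (worse_run > 0 && resid > 3 * best) {
      mix <- max(mix / 2, 1e-4); worse_run <- 0; stable_run <- 0
      aaX <- aaF <- NULL   # restart the secant history after instability
    } else if (stable_run >= 200) {
      mix <- min(2 * mix, ctl$mix_max); stable_run <- 0
    }
    xk <- as.numeric(rho); fk <- as.numeric(rhs) - xk
    use_aa <- aa_m > 0 && it > ctl$warmup
    if (use_aa && !is.null(x_prev)) {
      aaX <- cbind(aaX, xk - x_prev); aaF <- cbind(aaF, fk - f_prev)
      if (ncol(aaF) > aa_m) { aaX <- aaX[, -1, drop = FALSE]
                              aaF <- aaF[, -1, drop = FALSE] }
    }
    x_prev <- xk; f_prev <- fk
    if (use_aa && !is.null(aaF) && ncol(aaF) >= 1) {
      gam <- tryCatch(qr.solve(qr(aaF, LAPACK = TRUE), fk),
                      error = function(e) NULL)
      if (!is.null(gam) && all(is.finite(gam)) &&
          sqrt(sum(gam^2)) < 1e3) {
        if (is.na(aa_beta)) aa_beta <- max(mix, 0.1)
        beta <- aa_beta
        xn <- xk + beta * fk - (aaX + beta * aaF) %*% gam
        rho_n <- matrix(pmax(as.numeric(xn), 0), ncol = ns) * alive
        rho <- rho_n
        next
      }
    }
    rho <- (1 - mix) * rho + mix * rhs
  }
  psi <- mep_from_profiles(list(grid = grid, rho = rho), spec)
  out <- structure(list(grid = grid, rho = rho, psi = psi,
                        converged = converged, residual_history = res_hist,
                        iterations = length(res_hist), mixing_final = mix,
                        spec = spec, controls = ctl, model = "dft"),
                   class = "sdl_profiles")
  if (!converged)
    warning("DFT not converged after ", ctl$max_iter,
            " iterations (residual ", signif(utils::tail(res_hist, 1), 3),
            "); partial result returned")
  out
}

#' @export
print.sdl_profiles <- function(x, ...) {
  cat(sprintf("%s profiles: %d nodes on [%.4g, %.4g] nm, h = %.4g nm\n",
              x$model, x$grid$n, x$grid$R, x$grid$rmax, x$grid$h))
  cat(sprintf("  converged: %s (%d iterations)\n", x$converged,
              if (!is.null(x$iterations)) x$iterations else NA_integer_))
  cat(sprintf("  psi(R) = %.5g kT/e\n", x$psi[1]))
  invisible(x)
}
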