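## Canonical-cell correspondence for DFT <-> MC cross-validation.
##
## A canonical simulation cell holds fixed particle numbers, so its far field
## is generally not the nominal reservoir: part of the macroion's
## countercharge still resides near the cell boundary.  For a like-for-like
## comparison the DFT reservoir concentrations are fixed by requiring that
## the open-system profiles, integrated over the simulation cube, reproduce
## the simulated particle counts.

## fraction of the sphere of radius r (centered in a cube of edge L) lying
## inside the cube; deterministic angular quadrature on an octant grid
.sphere_in_cube_fraction <- function(r, L, ntheta = 64, nphi = 64) {
  th <- (seq_len(ntheta) - 0.5) / ntheta * (pi / 2)
  ph <- (seq_len(nphi) - 0.5) / nphi * (pi / 4)  # octant + mirror symmetry
  g <- expand.grid(th = th, ph = ph)
  ux <- sin(g$th) * cos(g$ph); uy <- sin(g$th) * sin(g$ph); uz <- cos(g$th)
  rmax_dir <- (L / 2) / pmax(ux, uy, uz)
  w <- sin(g$th); w <- w / sum(w)
  vapply(r, function(ri) sum(w[rmax_dir >= ri]), numeric(1))
}

## particle counts predicted by a profile set for a cubic cell of edge L
## (profiles continued at bulk beyond their grid)
.cell_counts <- function(prof, spec, L) {
  rho_b <- sp_density(spec)
  rmaxc <- sqrt(3) * L / 2
  h <- prof$grid$h
  r <- seq(prof$grid$R, rmaxc, by = h)
  f <- .sphere_in_cube_fraction(r, L)
  sapply(seq_along(rho_b), function(a) {
    d <- stats::approx(prof$grid$r, prof$rho[, a], xout = r,
                       yleft = 0, yright = rho_b[a])$y
    sum(4 * pi * .trapw(length(r), h) * r^2 * d * f)
  })
}

#' Match DFT reservoir concentrations to a canonical simulation cell
#'
#' Iteratively rescales the reservoir (bulk) concentrations until the DFT
#' profiles, integrated over the cubic cell, reproduce the given particle
#' counts.  The coion concentration is slaved to bulk electroneutrality at
#' every step.
#'
#' @param spec Starting \code{sdl_system} (nominal concentrations).
#' @param L Cube edge (nm).
#' @param counts Integer particle counts per species (as simulated).
#' @param grid,controls Passed to \code{\link{solve_dft}}.
#' @param tol Relative count mismatch to stop at (default 0.01).
#' @param max_iter Outer iterations (default 8).
#' @return List with the matched \code{spec}, the final \code{profiles} and
#'   the achieved relative count \code{mismatch}.
#' @export
match_cell_concentrations <- function(spec, L, counts, grid = NULL,
                                      controls = list(), tol = 0.01,
                                      max_iter = 8) {
  z <- sp_valence(spec); sig <- sp_sigma(spec)
  labs <- sp_label(spec)
  ZM <- round(spec$macroion$valence)
  conc <- vapply(spec$species, `[[`, numeric(1), "concentration")
  ## identify the coion slaved to neutrality: the ion whose sign matches Z_M
  ## (or the most abundant ion for an uncharged macroion)
  co <- if (ZM != 0) which(sign(z) == sign(ZM))[1] else which(z != 0)[1]
  free <- setdiff(seq_along(z), co)
  prof <- NULL; mism <- Inf
  for (it in seq_len(max_iter)) {
    spl <- lapply(seq_along(z), function(a)
      species(labs[a], sig[a], z[a], conc[a]))
    spm <- system_spec(spl, spec$macroion, eps = spec$eps,
                       temperature = spec$temperature)
    prof <- solve_dft(spm, grid, controls)
    pred <- .cell_counts(prof, spm, L)
    ## small counts are quantized (rounded at setup); judge them on an
    ## absolute scale of a fraction of a particle
    mism <- max(abs(pred - counts) / pmax(counts, 20))
    if (mism < tol) return(list(spec = spm, profiles = prof,
                                mismatch = mism, iterations = it))
    fac <- counts / pmax(pred, 1e-10)
    conc[free] <- conc[free] * pmin(pmax(fac[free], 0.3), 3)
    if (ZM != 0)
      conc[co] <- -sum(z[free] * molar_to_number_density(conc[free])) /
        z[co] / molar_to_number_density(1)
  }
  warning("cell-count matching stopped at relative mismatch ",
          signif(mism, 3))
  list(spec = spm, profiles = prof, mismatch = mism, iterations = max_iter)
}

#' Volume-weighted bin averages of a radial profile
#'
#' Averages a fine-grid profile over the spherical bins of a simulation
#' report (half-open bins, r^2 weighting), for like-for-like comparison with
#' binned Monte Carlo densities.
#'
#' @param r_fine,f Fine grid and values.
#' @param edges Bin edges (length nbins + 1).
#' @return Vector of bin averages.
#' @export
bin_average_profile <- function(r_fine, f, edges) {
  nb <- length(edges) - 1
  out <- numeric(nb)
  eps <- 1e-9
  for (k in seq_len(nb)) {
    m <- r_fine >= edges[k] - eps & r_fine < edges[k + 1] - eps
    if (sum(m) < 2) {
      out[k] <- stats::approx(r_fine, f, xout = (edges[k] + edges[k + 1]) / 2,
                              rule = 2)$y
    } else {
      w <- r_fine[m]^2
      out[k] <- sum(f[m] * w) / sum(w)
    }
  }
  out
}
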