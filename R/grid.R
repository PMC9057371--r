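#' Uniform radial grid from the macroion surface
#'
#' @param R Inner radius (macroion surface) in nm.
#' @param rmax Outer truncation radius in nm.
#' @param h Grid step in nm.
#' @return An object of class \code{sdl_grid} with node positions \code{r}.
#' @export
radial_grid <- function(R, rmax, h) {
  stopifnot(R > 0, rmax > R, h > 0)
  n <- ceiling((rmax - R) / h)
  r <- R + h * (0:n)
  structure(list(r = r, h = h, R = R, rmax = r[length(r)], n = length(r)),
            class = "sdl_grid")
}

## default grid for a system: step sigma_min/40, extent the larger of 10
## Debye lengths and 8 large-ion diameters beyond the surface
default_grid <- function(spec, h = NULL, rmax = NULL) {
  sig <- sp_sigma(spec); rho <- sp_density(spec)
  sigs <- sig[rho > 0]
  kap <- debye_kappa(spec)
  if (is.null(h)) h <- min(sigs) / 40
  if (is.null(rmax))
    rmax <- spec$macroion$radius +
      max(if (kap > 0) 10 / kap else 0, 8 * max(sigs), 2)
  radial_grid(spec$macroion$radius, rmax, h)
}

## trapezoid weights for a uniform grid
.trapw <- function(n, h) {
  w <- rep(h, n); w[1] <- h / 2; w[n] <- h / 2
  w
}

## cumulative trapezoid integral, same length as x, starting at 0
.cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}
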