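## Spherically symmetric 3D convolution on a radial grid.
##
## For radial f and kernel K,
##   (f * K)(r) = (2 pi / r) int dr' r' f(r') [Jc(r + r') - Jc(|r - r'|)]
## with Jc(x) = int_0^x s K(s) ds, both integrals by the trapezoid rule.
## Compact kernels are tabulated once (Jc on a fine mesh) and the whole
## operator becomes a dense matrix applied per iteration.

## cumulative kernel integral Jc for a compactly supported kernel given by a
## function K(s) on (0, reach]; returns a lookup closure
.kernel_cumint <- function(K, reach, h) {
  hf <- reach / max(64, 4 * ceiling(reach / h))
  sf <- seq(0, reach, by = hf)
  if (sf[length(sf)] < reach) sf <- c(sf, reach)
  sk <- sf * K(sf)
  sk[1] <- 0  # s*K(s) -> finite or 0; at s=0 the measure vanishes
  Jc <- .cumtrapz(sf, sk)
  Jtot <- Jc[length(Jc)]
  list(fun = stats::approxfun(sf, Jc, yleft = 0, yright = Jtot),
       total = Jtot, reach = reach)
}

## dense convolution operator matrix: rows = output nodes r_out (main grid),
## cols = input nodes r_in (extended grid, uniform step h).
## If normalize_to is finite, each row is scaled so that a constant unit input
## maps to exactly normalize_to (discrete normalization; used for WDA weights
## where the analytic integral is 1).
.conv_operator <- function(r_out, r_in, h, cumint, normalize_to = NA) {
  w <- .trapw(length(r_in), h)
  A <- outer(r_out, r_in, "+")
  B <- abs(outer(r_out, r_in, "-"))
  W <- (cumint$fun(A) - cumint$fun(B)) *
    matrix(w * r_in, nrow = length(r_out), ncol = length(r_in), byrow = TRUE)
  W <- W * (2 * pi / r_out)
  if (!is.na(normalize_to)) {
    rs <- rowSums(W)
    ok <- abs(rs) > 1e-300
    W[ok, ] <- W[ok, ] * (normalize_to / rs[ok])
  }
  W
}

#' Spherical convolution of a radial field with a radial kernel
#'
#' Convenience single-shot interface (the solvers build the operator matrix
#' once and reuse it).  The input field must be given on the extended grid
#' covering the kernel reach beyond both ends of the output grid; fields that
#' decay to a constant should be continued at that constant by the caller.
#'
#' @param f Field values on \code{r_in}.
#' @param K Kernel function of separation s (vectorized), compactly supported
#'   on (0, reach].
#' @param reach Kernel support radius in nm.
#' @param r_out Output node positions.
#' @param r_in Input node positions (uniform step).
#' @param normalize If TRUE the kernel is taken as normalized (its 3D
#'   integral is 1) and the discrete operator is rescaled so that a constant
#'   input maps exactly to itself.
#' @return Values of (f * K) at \code{r_out}.
#' @export
spherical_convolution <- function(f, K, reach, r_out, r_in,
                                  normalize = FALSE) {
  h <- r_in[2] - r_in[1]
  ci <- .kernel_cumint(K, reach, h)
  W <- .conv_operator(r_out, r_in, h, ci,
                      normalize_to = if (normalize) 1 else NA)
  as.numeric(W %*% f)
}
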