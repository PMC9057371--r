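## Uniform hard-sphere mixture thermodynamics and the Percus-Yevick mixture
## direct correlation function, both derived from the scaled-particle
## (PY-compressibility) excess free energy density
##   Phi = -n0 ln(1-n3) + n1 n2/(1-n3) + n2^3/(24 pi (1-n3)^2)
## with the usual weighted moments n_k of the density vector.  Writing the
## pair DCF as the weight-function convolution of the same Phi guarantees
## exact thermodynamic consistency d c1_i / d rho_j = int c2_ij d3s.

.hs_moments <- function(rho, sig) {
  R <- sig / 2
  list(n0 = sum(rho), n1 = sum(rho * R), n2 = sum(rho * 4 * pi * R^2),
       n3 = sum(rho * 4 * pi / 3 * R^3))
}

## first derivatives dPhi/dn_k (uniform fluid)
.phi_grad <- function(n) {
  D <- 1 - n$n3
  if (D <= 0) stop("total packing fraction >= 1")
  c(-log(D),
    n$n2 / D,
    n$n1 / D + n$n2^2 / (8 * pi * D^2),
    n$n0 / D + n$n1 * n$n2 / D^2 + n$n2^3 / (12 * pi * D^3))
}

## second derivatives d2Phi/dn_a dn_b (scalar block) and the vector-weight
## second derivatives at n_v = 0
.phi_hess <- function(n) {
  D <- 1 - n$n3
  if (D <= 0) stop("total packing fraction >= 1")
  H <- matrix(0, 4, 4)
  H[1, 4] <- H[4, 1] <- 1 / D
  H[2, 3] <- H[3, 2] <- 1 / D
  H[2, 4] <- H[4, 2] <- n$n2 / D^2
  H[3, 3] <- n$n2 / (4 * pi * D^2)
  H[3, 4] <- H[4, 3] <- n$n1 / D^2 + n$n2^2 / (4 * pi * D^3)
  H[4, 4] <- n$n0 / D^2 + 2 * n$n1 * n$n2 / D^3 + n$n2^3 / (4 * pi * D^4)
  list(H = H, v1v2 = -1 / D, v2v2 = -n$n2 / (4 * pi * D^2))
}

## weight-moment vector xi^i = (1, R_i, 4 pi R_i^2, 4 pi R_i^3 / 3)
.hs_xi <- function(sig) {
  R <- sig / 2
  rbind(rep(1, length(R)), R, 4 * pi * R^2, 4 * pi / 3 * R^3)
}

#' Uniform hard-sphere one-particle direct correlation functions
#'
#' Returns c1_hs,a = -beta mu_ex,a for each species of a uniform hard-sphere
#' mixture, from the PY-compressibility (scaled-particle) equation of state.
#'
#' @param rho Number densities in nm^-3 (vector, one per species).
#' @param sig Hard-sphere diameters in nm.
#' @return Vector of dimensionless c1 values (zero at zero density).
#' @export
uniform_c1_hs <- function(rho, sig) {
  stopifnot(length(rho) == length(sig), all(rho >= 0))
  n <- .hs_moments(rho, sig)
  g <- .phi_grad(n)
  -as.numeric(crossprod(.hs_xi(sig), g))
}

## d c1_i / d rho_j = -d2(beta f_ex)/d rho_i d rho_j ; equals (exactly)
## the 3D integral of the PY pair DCF over s.
dc1_hs_drho <- function(rho, sig) {
  n <- .hs_moments(rho, sig)
  h <- .phi_hess(n)
  xi <- .hs_xi(sig)
  -t(xi) %*% h$H %*% xi
}

## geometric overlap kernels (convolutions of FMT weight functions);
## all vectorized over r >= 0
.ov_shell_shell <- function(r, Ri, Rj) {
  out <- numeric(length(r))
  m <- r >= abs(Ri - Rj) & r <= Ri + Rj & r > 0
  out[m] <- 2 * pi * Ri * Rj / r[m]
  out
}
.ov_shell_ball <- function(r, Ri, Rj) {  # surface of sphere Ri inside ball Rj
  out <- numeric(length(r))
  out[r < Rj - Ri] <- 4 * pi * Ri^2
  m <- r >= abs(Ri - Rj) & r <= Ri + Rj & r > 0
  out[m] <- pi * Ri * (Rj^2 - (r[m] - Ri)^2) / r[m]
  out
}
.ov_ball_ball <- function(r, Ri, Rj) {   # lens volume of two balls
  out <- numeric(length(r))
  out[r <= abs(Ri - Rj)] <- 4 * pi / 3 * min(Ri, Rj)^3
  m <- r > abs(Ri - Rj) & r < Ri + Rj
  rr <- r[m]
  out[m] <- pi * (Ri + Rj - rr)^2 *
    (rr^2 + 2 * rr * (Ri + Rj) - 3 * (Ri - Rj)^2) / (12 * rr)
  out
}
.ov_vv <- function(r, Ri, Rj) {          # vector-weight (normal.normal) overlap
  out <- numeric(length(r))
  m <- r >= abs(Ri - Rj) & r <= Ri + Rj & r > 0
  out[m] <- pi * (Ri^2 + Rj^2 - r[m]^2) / r[m]
  out
}

#' Percus-Yevick pair direct correlation function of a hard-sphere mixture
#'
#' Closed-form additive-mixture PY (compressibility-route) DCF, assembled from
#' the scaled-particle free energy and its geometric weight functions.
#' Identically zero beyond contact and symmetric in (i, j).
#'
#' @param rho Densities (nm^-3) of all species.
#' @param sig Diameters (nm) of all species.
#' @param i,j Species indices (1-based).
#' @param s Separation(s) in nm.
#' @return Dimensionless kernel values (vectorized over s).
#' @export
py_hs_dcf <- function(rho, sig, i, j, s) {
  stopifnot(all(s >= 0), length(rho) == length(sig))
  ## the 1/s overlap pieces cancel analytically as s -> 0; evaluate the
  ## origin at an equivalent tiny separation
  s[s == 0] <- 1e-9 * (sig[i] + sig[j]) / 2
  n <- .hs_moments(rho, sig)
  h <- .phi_hess(n)
  Ri <- sig[i] / 2; Rj <- sig[j] / 2
  ss <- .ov_shell_shell(s, Ri, Rj)
  sb <- .ov_shell_ball(s, Ri, Rj)
  bs <- .ov_shell_ball(s, Rj, Ri)
  bb <- .ov_ball_ball(s, Ri, Rj)
  vv <- .ov_vv(s, Ri, Rj)
  wfac <- function(al, R) switch(al, `1` = 1 / (4 * pi * R^2),
                                     `2` = 1 / (4 * pi * R), `3` = 1)
  cval <- numeric(length(s))
  for (a in 1:4) for (b in 1:4) {
    dd <- h$H[a, b]
    if (dd == 0) next
    base <- if (a <= 3 && b <= 3) ss * wfac(as.character(a), Ri) *
              wfac(as.character(b), Rj)
            else if (a <= 3) sb * wfac(as.character(a), Ri)
            else if (b <= 3) bs * wfac(as.character(b), Rj)
            else bb
    cval <- cval - dd * base
  }
  cval <- cval - h$v1v2 * (vv / (4 * pi * Ri) + vv / (4 * pi * Rj)) -
    h$v2v2 * vv
  cval[s > Ri + Rj] <- 0
  cval
}
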