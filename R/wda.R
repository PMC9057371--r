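## Denton-Ashcroft weighted-density approximation, mixture form: the
## nonuniform hard-sphere one-particle DCF of species a at r is the uniform
## c1_hs,a evaluated at the vector of weighted densities
##   rhobar_a(r) = sum_b int d3r' rho_b(r') w_ab(|r - r'|; D)
## with the weight the normalized PY pair DCF,
##   w_ab(s; D) = c2_hs,ab(s; D) / [d c1_hs,a / d rho_b](D),
## whose normalization int w d3s = 1 is an exact identity of the
## PY-compressibility pair/one-particle consistency.  D is the bulk density
## vector (mode "bulk_weights", default) or the local weighted densities
## themselves (mode "self_consistent").

#' DA weight kernel for a species pair
#'
#' @param i,j Species indices (the kernel is not symmetric under i <-> j).
#' @param s Separation(s) in nm.
#' @param rho Density vector (nm^-3) at which the weight is evaluated.
#' @param sig Diameter vector (nm).
#' @return Kernel values in nm^-3 (integrates to 1 over 3D space).  At zero
#'   densities the PY kernel degenerates and the uniform normalized kernel
#'   over the contact sphere is returned (the exact zero-density limit).
#' @export
weight_kernel <- function(i, j, s, rho, sig) {
  stopifnot(all(s >= 0))
  contact <- (sig[i] + sig[j]) / 2
  den <- dc1_hs_drho(rho, sig)[i, j]
  if (abs(den) < 1e-14 || sum(rho) == 0) {
    ## zero-density limit: c2 -> -1 inside contact, denominator -> -V_contact
    out <- numeric(length(s))
    out[s <= contact] <- 1 / (4 * pi / 3 * contact^3)
    return(out)
  }
  py_hs_dcf(rho, sig, i, j, s) / den
}

## stacked bulk-weight convolution operator for all (a,b) pairs:
## rows: ns blocks of length(r_out); cols: ns blocks of length(r_in).
## Rows are discretely normalized so that uniform bulk input reproduces the
## bulk densities exactly.
.build_wda_operator <- function(spec, r_out, r_in) {
  rho <- sp_density(spec); sig <- sp_sigma(spec)
  ns <- length(rho); h <- r_in[2] - r_in[1]
  no <- length(r_out); ni <- length(r_in)
  M <- matrix(0, ns * no, ns * ni)
  for (a in seq_len(ns)) for (b in seq_len(ns)) {
    reach <- (sig[a] + sig[b]) / 2
    ci <- .kernel_cumint(function(s) weight_kernel(a, b, s, rho, sig),
                         reach, h)
    W <- .conv_operator(r_out, r_in, h, ci, normalize_to = 1)
    M[(a - 1) * no + seq_len(no), (b - 1) * ni + seq_len(ni)] <- W
  }
  M
}

## evaluate c1_hs for a matrix of density vectors (columns = species),
## vectorized over rows; returns matrix (nrow x ns)
.c1_hs_field <- function(rhobar_mat, sig) {
  R <- sig / 2
  n0 <- rowSums(rhobar_mat)
  n1 <- as.numeric(rhobar_mat %*% R)
  n2 <- as.numeric(rhobar_mat %*% (4 * pi * R^2))
  n3 <- as.numeric(rhobar_mat %*% (4 * pi / 3 * R^3))
  n3 <- pmin(n3, 0.95)  # guard against transient over-packed iterates
  D <- 1 - n3
  g0 <- -log(D)
  g1 <- n2 / D
  g2 <- n1 / D + n2^2 / (8 * pi * D^2)
  g3 <- n0 / D + n1 * n2 / D^2 + n2^3 / (12 * pi * D^3)
  xi <- .hs_xi(sig)
  -(outer(g0, xi[1, ]) + outer(g1, xi[2, ]) + outer(g2, xi[3, ]) +
      outer(g3, xi[4, ]))
}

## apply the stacked WDA operator to profiles: returns array (nodes, a, b)
## with [., a, b] the b-th density smoothed by the (a,b) weight
.wda_apply <- function(M, ext_rho, no, ns) {
  ni <- nrow(ext_rho)
  D <- matrix(0, ns * ni, ns)
  for (b in seq_len(ns)) D[(b - 1) * ni + seq_len(ni), b] <- ext_rho[, b]
  V <- M %*% D                      # (ns*no) x ns ; row block a, column b
  arr <- array(0, c(no, ns, ns))
  for (a in seq_len(ns)) arr[, a, ] <- V[(a - 1) * no + seq_len(no), ]
  arr
}

#' Weighted densities of a set of radial profiles
#'
#' One weighted density per species pair: \code{rhobar[r, a, b]} is the b-th
#' density profile smoothed with the (a,b) Denton-Ashcroft weight; species a's
#' hard-sphere one-particle DCF is the uniform function evaluated at the
#' density vector \code{rhobar[r, a, ]}.  For uniform input every slice equals
#' the corresponding bulk density.
#'
#' @param profiles A \code{sdl_profiles} object (see
#'   \code{\link{solve_dft}}) or a list with elements \code{grid} and
#'   \code{rho} (matrix, nodes x species).
#' @param spec The \code{sdl_system}.
#' @param mode "bulk_weights" (default) or "self_consistent".
#' @param tol Inner fixed-point tolerance for the self-consistent mode.
#' @return A list with \code{r} and array \code{rhobar} (nodes x species x
#'   species).
#' @export
weighted_density_profile <- function(profiles, spec, mode = c("bulk_weights",
                                     "self_consistent"), tol = 1e-8) {
  mode <- match.arg(mode)
  grid <- profiles$grid
  rho_b <- sp_density(spec); sig <- sp_sigma(spec)
  ns <- length(rho_b)
  ext <- .extend_profiles(profiles$rho, grid, spec)
  if (mode == "bulk_weights") {
    M <- .build_wda_operator(spec, grid$r, ext$r)
    rb <- .wda_apply(M, ext$rho, grid$n, ns)
  } else {
    rb <- .wda_self_consistent(ext, grid, spec, tol)
  }
  list(r = grid$r, rhobar = rb)
}

## self-consistent DA mode: at each output node the weights are evaluated at
## the local weighted-density vector (damped inner fixed point).
.wda_self_consistent <- function(ext, grid, spec, tol, max_iter = 200) {
  rho_b <- sp_density(spec); sig <- sp_sigma(spec)
  ns <- length(rho_b); h <- ext$r[2] - ext$r[1]
  r_out <- grid$r
  rb <- array(rep(rho_b, each = length(r_out) * ns),
              c(length(r_out), ns, ns))  # start from bulk
  scale <- max(rho_b) + 1e-300
  resid_hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    rb_new <- rb
    for (k in seq_along(r_out)) {
      for (a in seq_len(ns)) {
        d <- pmax(rb[k, a, ], 0)  # weights evaluated at the local field
        for (b in seq_len(ns)) {
          reach <- (sig[a] + sig[b]) / 2
          ci <- .kernel_cumint(function(s) weight_kernel(a, b, s, d, sig),
                               reach, h)
          W <- .conv_operator(r_out[k], ext$r, h, ci, normalize_to = 1)
          rb_new[k, a, b] <- as.numeric(W %*% ext$rho[, b])
        }
      }
    }
    resid <- max(abs(rb_new - rb)) / scale
    resid_hist <- c(resid_hist, resid)
    rb <- 0.5 * rb + 0.5 * rb_new
    if (resid < tol) return(rb)
  }
  stop("self-consistent weighted density did not converge; residual history: ",
       paste(signif(utils::tail(resid_hist, 5), 3), collapse = ", "))
}

#' Hard-sphere one-particle DCF profile from weighted densities
#'
#' @param field Output of \code{\link{weighted_density_profile}}.
#' @param spec The system.
#' @return Matrix (nodes x species) of c1_hs values; subtract
#'   \code{uniform_c1_hs} at bulk to get the Eq.-5 difference.
#' @export
c1_hs_profile <- function(field, spec) {
  sig <- sp_sigma(spec)
  ns <- length(sig)
  nr <- dim(field$rhobar)[1]
  out <- matrix(0, nr, ns)
  for (a in seq_len(ns))
    out[, a] <- .c1_hs_field(matrix(field$rhobar[, a, ], nr, ns), sig)[, a]
  out
}

## extend profiles onto the padded grid used by the convolution operators:
## zero below the macroion surface, bulk beyond rmax
.extend_profiles <- function(rho_mat, grid, spec) {
  sig <- sp_sigma(spec); rho_b <- sp_density(spec)
  ns <- length(rho_b); h <- grid$h
  pad <- max(outer(sig, sig, "+") / 2)
  nlo <- ceiling(pad / h); nhi <- ceiling(pad / h)
  rlo_start <- grid$R - nlo * h
  if (rlo_start <= h) { nlo <- floor((grid$R - h) / h); rlo_start <- grid$R - nlo * h }
  r_ext <- c(rlo_start + h * (0:(nlo - 1)), grid$r,
             grid$rmax + h * seq_len(nhi))
  m <- matrix(0, length(r_ext), ns)
  idx <- nlo + seq_len(grid$n)
  m[idx, ] <- rho_mat
  m[nlo + grid$n + seq_len(nhi), ] <- matrix(rho_b, nhi, ns, byrow = TRUE)
  list(r = r_ext, rho = m, main_idx = idx)
}
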