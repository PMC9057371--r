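## Mean spherical approximation for the bulk size- and charge-asymmetric
## primitive-model mixture (neutral hard spheres included).
##
## The screening parameter Gamma, the auxiliary P_n and the effective charges
## X_i follow Blum's analytic closure.  The electrostatic pair DCF is exactly
## -lambda_B z_i z_j / s beyond contact; inside the core it is obtained from a
## spectral (Fourier) solution of the defining equations of the MSA
## (Ornstein-Zernike with h = -1 inside the cores and c = -beta u outside),
## minus the analytic PY hard-sphere part.  The restricted equal-diameter
## closed form is used as an independent oracle in the tests.

#' Debye screening parameter of a system
#'
#' kappa = sqrt(4 pi lambda_B sum_i rho_i z_i^2), in 1/nm.
#'
#' @param spec An \code{sdl_system}.
#' @return kappa in nm^-1 (0 for an uncharged system).
#' @export
debye_kappa <- function(spec) {
  rho <- sp_density(spec); z <- sp_valence(spec)
  sqrt(4 * pi * spec$lambda_B * sum(rho * z^2))
}

#' Solve Blum's MSA closure for the screening parameter Gamma
#'
#' Damped fixed-point iteration started from the exact upper bound kappa/2
#' (the point-ion limit).  For an entirely uncharged system Gamma = 0 and the
#' electrostatic kernels vanish identically.
#'
#' @param spec An \code{sdl_system}.
#' @param tol Relative tolerance on Gamma.
#' @param max_iter Iteration cap.
#' @return An object of class \code{msa_parameters} with fields gamma, p_n,
#'   delta, x_i, kappa.
#' @export
solve_msa_gamma <- function(spec, tol = 1e-13, max_iter = 1e4) {
  rho <- sp_density(spec); sig <- sp_sigma(spec); z <- sp_valence(spec)
  lam <- spec$lambda_B
  kap <- debye_kappa(spec)
  Delta <- 1 - pi / 6 * sum(rho * sig^3)
  out <- list(kappa = kap, delta = Delta)
  if (kap == 0) {
    out$gamma <- 0; out$p_n <- 0; out$x_i <- z
    class(out) <- "msa_parameters"
    return(out)
  }
  G <- kap / 2
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    Om <- 1 + pi / (2 * Delta) * sum(rho * sig^3 / (1 + G * sig))
    Pn <- sum(rho * sig * z / (1 + G * sig)) / Om
    X  <- (z - pi / (2 * Delta) * Pn * sig^2) / (1 + G * sig)
    Gn <- sqrt(pi * lam * sum(rho * X^2))
    if (abs(Gn - G) < tol * G) { G <- Gn; conv <- TRUE; break }
    G <- 0.5 * G + 0.5 * Gn
  }
  if (!conv) stop("MSA Gamma iteration did not converge; last Gamma = ", G)
  Om <- 1 + pi / (2 * Delta) * sum(rho * sig^3 / (1 + G * sig))
  Pn <- sum(rho * sig * z / (1 + G * sig)) / Om
  X  <- (z - pi / (2 * Delta) * Pn * sig^2) / (1 + G * sig)
  out$gamma <- G; out$p_n <- Pn; out$x_i <- X
  class(out) <- "msa_parameters"
  out
}

## ---- spectral bulk MSA solution -------------------------------------------

## discrete sine transform (DST-I, plain sum convention) via the FFT of the
## odd extension; input length N, fft length 2N+2 (choose N = 2^p - 1)
.dst1 <- function(x) {
  N <- length(x)
  y <- c(0, x, 0, -rev(x))
  -Im(stats::fft(y))[2:(N + 1)] / 2
}

## solve H = (I - C D)^{-1} C for every k at once; C is array (ns,ns,N)
.batch_oz_solve <- function(C, rho) {
  ns <- dim(C)[1]; N <- dim(C)[3]
  A <- array(0, dim(C))
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    A[i, j, ] <- -C[i, j, ] * rho[j]
    if (i == j) A[i, j, ] <- A[i, j, ] + 1
  }
  B <- C
  ## vectorized Gaussian elimination without pivoting (A diagonally dominant
  ## for physical states)
  for (p in seq_len(ns)) {
    piv <- A[p, p, ]
    for (j in seq_len(ns)) {
      A[p, j, ] <- A[p, j, ] / piv
      B[p, j, ] <- B[p, j, ] / piv
    }
    ## note: divide B row AFTER A row normalization is fine since independent
    for (i in seq_len(ns)) {
      if (i == p) next
      f <- A[i, p, ]
      if (all(f == 0)) next
      for (j in seq_len(ns)) {
        A[i, j, ] <- A[i, j, ] - f * A[p, j, ]
        B[i, j, ] <- B[i, j, ] - f * B[p, j, ]
      }
    }
  }
  B
}

## Exact spectral solution of the bulk MSA: returns the full pair DCF tables
## on the solver mesh.  Deterministic given the state and mesh controls.
.msa_oz_solve <- function(rho, sig, z, lam,
                          dr = NULL, N = NULL, alpha = NULL,
                          mix = 0.3, tol = 1e-11, max_iter = 4e4) {
  ns <- length(rho)
  sijm <- outer(sig, sig, "+") / 2
  if (is.null(dr)) dr <- max(2e-4, min(2e-3, min(sig[rho > 0]) / 128))
  kap <- sqrt(4 * pi * lam * sum(rho * z^2))
  G2 <- if (kap > 0) {
    gg <- solve_msa_gamma(structure(list(
      species = lapply(seq_len(ns), function(i)
        list(diameter = sig[i], valence = z[i], density = rho[i],
             label = "x", concentration = 0)),
      lambda_B = lam), class = "sdl_system"))
    gg$gamma
  } else Inf
  rmax_need <- max(8 * max(sig), if (is.finite(G2)) 6 / G2 else 0,
                   3 * max(sig) + 2)
  if (is.null(N)) {
    p <- ceiling(log2(rmax_need / dr + 1))
    p <- min(max(p, 10), 17)
    N <- 2^p - 1
  }
  if (is.null(alpha)) alpha <- min(12, max(1.5, 2 / min(sig)))
  r <- dr * seq_len(N)
  dk <- pi / (dr * (N + 1))
  k <- dk * seq_len(N)
  ftp <- 4 * pi * dr / k          # forward prefactor (applied to dst of r*f)
  ifp <- dk / (2 * pi^2 * r)      # inverse prefactor (applied to dst of k*F)
  clk <- exp(-k^2 / (4 * alpha^2)) / k^2   # FT of erf(alpha r)/r over 4 pi
  erfa <- 2 * stats::pnorm(alpha * r * sqrt(2)) - 1  # erf(alpha r)
  zz <- outer(z, z)
  inside <- lapply(seq_len(ns), function(i) lapply(seq_len(ns), function(j)
    r < sijm[i, j]))
  cs <- array(0, c(ns, ns, N))
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    ins <- inside[[i]][[j]]
    cs[i, j, !ins] <- -lam * zz[i, j] * (1 - erfa[!ins]) / r[!ins]
    cs[i, j, ins] <- -1 + lam * zz[i, j] * erfa[ins] / r[ins]
  }
  Cs <- array(0, c(ns, ns, N))
  err_hist <- numeric(0)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    for (i in seq_len(ns)) for (j in seq_len(ns)) {
      if (j < i) { Cs[i, j, ] <- Cs[j, i, ]; next }
      Cs[i, j, ] <- ftp * .dst1(r * cs[i, j, ])
    }
    C <- Cs
    for (i in seq_len(ns)) for (j in seq_len(ns))
      C[i, j, ] <- C[i, j, ] - 4 * pi * lam * zz[i, j] * clk
    H <- .batch_oz_solve(C, rho)
    err <- 0
    for (i in seq_len(ns)) for (j in seq_len(ns)) {
      if (j < i) next
      gs <- ifp * .dst1(k * (H[i, j, ] - Cs[i, j, ]))   # gamma_s = h - c_s
      ins <- inside[[i]][[j]]
      tgt <- -1 - gs[ins]
      err <- max(err, max(abs(tgt - cs[i, j, ins])))
      upd <- (1 - mix) * cs[i, j, ins] + mix * tgt
      cs[i, j, ins] <- upd
      if (i != j) cs[j, i, ins] <- upd
    }
    err_hist <- c(err_hist, err)
    if (err < tol) { conv <- TRUE; break }
    if (it > 60 && err > 10 * min(err_hist)) {
      mix <- mix / 2
      if (mix < 1e-3)
        stop("bulk MSA spectral solve diverged (residual ", signif(err, 3), ")")
    }
  }
  if (!conv)
    stop("bulk MSA spectral solve: no convergence after ", max_iter,
         " iterations (residual ", signif(err, 3), ")")
  cfull <- cs
  for (i in seq_len(ns)) for (j in seq_len(ns))
    cfull[i, j, ] <- cs[i, j, ] - lam * zz[i, j] * erfa / r
  list(r = r, c = cfull, iterations = it, residual = err, dr = dr, N = N)
}

## analytic shell-overlap closed form for the el DCF inside the core:
## Coulomb interaction of two uniformly charged shells of radius
## a_i = (sigma_i + 1/Gamma)/2.  Exact for equal diameters (Waisman-Lebowitz
## in Gamma form) and exact in the point-ion limit; used as the fallback when
## the cores are too small to resolve spectrally.
.el_shell_form <- function(lam, zi, zj, si, sj, G, s) {
  if (G <= 0 || zi * zj == 0) return(numeric(length(s)))
  ai <- (si + 1 / G) / 2; aj <- (sj + 1 / G) / 2
  lo <- abs(ai - aj)
  v <- numeric(length(s))
  m <- s >= lo
  v[m] <- (-s[m]^2 + 2 * s[m] * (ai + aj) - (ai - aj)^2) / (4 * ai * aj * s[m])
  v[!m] <- 1 / max(ai, aj)
  -lam * zi * zj * v
}

## package-local cache for spectral kernel tables
.kernel_cache <- new.env(parent = emptyenv())

.spec_state <- function(spec) {
  list(rho = sp_density(spec), sig = sp_sigma(spec), z = sp_valence(spec),
       lam = spec$lambda_B)
}

## Electrostatic kernel tables for a system: per-pair el DCF inside the core
## on the solver mesh, plus metadata.  method is "spectral" or "shell".
msa_el_tables <- function(spec, params = solve_msa_gamma(spec)) {
  st <- .spec_state(spec)
  key <- paste(c(format(st$rho, digits = 15), format(st$sig, digits = 15),
                 st$z, format(st$lam, digits = 15)), collapse = "|")
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  ns <- length(st$rho)
  sijm <- outer(st$sig, st$sig, "+") / 2
  out <- list(contact = sijm, lam = st$lam, z = st$z, gamma = params$gamma)
  if (params$gamma == 0) {
    out$method <- "none"
  } else {
    dr <- max(2e-4, min(2e-3, min(st$sig[st$rho > 0]) / 128))
    rmax_need <- max(8 * max(st$sig), 6 / params$gamma, 3 * max(st$sig) + 2)
    if (rmax_need / dr + 1 > 2^17 || max(sijm) < 8 * dr) {
      out$method <- "shell"
    } else {
      sol <- .msa_oz_solve(st$rho, st$sig, st$z, st$lam)
      out$method <- "spectral"
      out$r <- sol$r
      out$iterations <- sol$iterations
      out$residual <- sol$residual
      tab <- vector("list", ns * ns)
      for (i in seq_len(ns)) for (j in seq_len(ns)) {
        ins <- sol$r < sijm[i, j]
        chs <- py_hs_dcf(st$rho, st$sig, i, j, sol$r[ins])
        tab[[(i - 1) * ns + j]] <- sol$c[i, j, ins] - chs
      }
      out$tab <- tab
      out$ns <- ns
    }
  }
  .kernel_cache[[key]] <- out
  out
}

#' Electrostatic part of the MSA pair direct correlation function
#'
#' Equals -lambda_B z_i z_j / s for s beyond contact (the MSA
#' exact-outside-core property); inside the core the kernel is the full MSA
#' DCF minus the PY hard-sphere part.  Note the MSA el DCF is discontinuous at
#' contact (as the restricted closed form already shows).
#'
#' @param params An \code{msa_parameters} object from
#'   \code{\link{solve_msa_gamma}}.
#' @param spec The \code{sdl_system}.
#' @param i,j Species indices.
#' @param s Separation(s) in nm (s >= 0).
#' @return Dimensionless kernel values.
#' @export
msa_el_dcf <- function(params, spec, i, j, s) {
  stopifnot(all(s >= 0))
  st <- .spec_state(spec)
  zi <- st$z[i]; zj <- st$z[j]
  sij <- (st$sig[i] + st$sig[j]) / 2
  out <- numeric(length(s))
  outm <- s >= sij
  out[outm] <- -st$lam * zi * zj / s[outm]
  if (any(!outm)) {
    if (params$gamma == 0) {
      out[!outm] <- 0
    } else {
      tabs <- msa_el_tables(spec, params)
      if (tabs$method == "spectral") {
        ns <- tabs$ns
        tb <- tabs$tab[[(i - 1) * ns + j]]
        rt <- tabs$r[seq_along(tb)]
        out[!outm] <- stats::approx(rt, tb, xout = s[!outm], rule = 2)$y
      } else {
        out[!outm] <- .el_shell_form(st$lam, zi, zj, st$sig[i], st$sig[j],
                                     params$gamma, s[!outm])
      }
    }
  }
  out
}

#' Dump the two-part DCF kernels of a pair to a columnar text file
#'
#' Columns: s_nm, c_hs, c_el (15 significant digits), for regression
#' snapshots and debugging.
#'
#' @param spec The system; \code{i,j} the species pair; \code{s} the mesh;
#'   \code{path} the output file.
#' @return The path, invisibly.
#' @export
dump_dcf_kernels <- function(spec, i, j, s, path) {
  params <- solve_msa_gamma(spec)
  chs <- py_hs_dcf(sp_density(spec), sp_sigma(spec), i, j, s)
  cel <- msa_el_dcf(params, spec, i, j, s)
  df <- data.frame(s_nm = s, c_hs = chs, c_el = cel)
  writeLines(c(sprintf("# dcf pair %d %d", i, j),
               paste(c("s_nm", "c_hs", "c_el"), collapse = " ")), path)
  utils::write.table(format(df, digits = 15, scientific = TRUE),
                     path, append = TRUE, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
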