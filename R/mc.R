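## R-level interface to the canonical Monte Carlo engine: configuration
## building, Ewald energy evaluation, Metropolis sweeps, spherical binning
## with block averaging.

#' Build an initial Monte Carlo configuration
#'
#' Fixes the macroion at the cell center and inserts the small ions and the
#' solvent by sequential random insertion with overlap rejection.  Particle
#' counts are N_a = round(rho_a L^3), with the coion count adjusted so the
#' cell is exactly electroneutral including the (rounded) macroion valence.
#'
#' @param spec The \code{sdl_system}.  The macroion valence is rounded to the
#'   nearest integer for exact cell neutrality.
#' @param L Cubic box edge in nm.
#' @param seed Integer RNG seed (recorded in the configuration).
#' @param max_attempts Insertion attempts per particle before giving up.
#' @return An object of class \code{sdl_mcconfig}.
#' @export
build_initial_configuration <- function(spec, L, seed = 1,
                                        max_attempts = 1e6) {
  sig <- sp_sigma(spec); z <- sp_valence(spec); rho_b <- sp_density(spec)
  ns <- length(sig)
  R <- spec$macroion$radius
  ZM <- round(spec$macroion$valence)
  kap <- debye_kappa(spec)
  if (kap > 0 && L < 2 * (R + 4 / kap))
    warning("box edge L = ", L, " nm below the recommended 2(R + 4/kappa) = ",
            signif(2 * (R + 4 / kap), 4), " nm")
  Nsp <- round(rho_b * L^3)
  ## adjust the coion count for exact neutrality (coion: charge of the same
  ## sign as the macroion; for an uncharged macroion, balance on the species
  ## with the largest count)
  imbal <- sum(z * Nsp) + ZM
  if (imbal != 0) {
    cand <- which(z != 0)
    if (length(cand) == 0) stop("charged macroion but no ionic species")
    ## pick the ion whose count change can absorb the imbalance exactly
    ok <- cand[imbal %% z[cand] == 0]
    if (length(ok) == 0) stop("cannot balance cell charge with integer counts")
    a <- ok[which.max(Nsp[ok])]
    Nsp[a] <- Nsp[a] - imbal / z[a]
    if (Nsp[a] < 0) stop("cell too small to neutralize the macroion")
  }
  stopifnot(sum(z * Nsp) + ZM == 0)
  spc <- rep(seq_len(ns) - 1L, Nsp)          # 0-based species tags
  rad <- rep(sig / 2, Nsp)
  set.seed(seed)
  pos <- mc_insert(rad, L, R, as.integer(max_attempts))
  structure(list(
    L = L, seed = seed,
    x = c(L / 2, pos[, 1]), y = c(L / 2, pos[, 2]), z = c(L / 2, pos[, 3]),
    q = c(ZM, z[spc + 1L]),
    rad = c(R, rad),
    spc = c(-1L, spc),
    mobile = c(FALSE, rep(TRUE, length(spc))),
    counts = stats::setNames(Nsp, sp_label(spec)),
    Z_M = ZM, spec = spec
  ), class = "sdl_mcconfig")
}

#' Ewald energy of a configuration
#'
#' Real-space sum (complementary error function, optionally over additional
#' image shells), reciprocal sum with conducting ("tin-foil") boundary
#' conditions, and the self term.  Energies in kT.
#'
#' @param config An \code{sdl_mcconfig} (or a list with x, y, z, q, rad, L).
#' @param alpha Splitting parameter in nm^-1; default 5.6/L.
#' @param kmax2 Reciprocal cutoff: include vectors with |n|^2 <= kmax2.
#' @param nshell Real-space image shells (0 = minimum image at cutoff L/2).
#' @return List with components real, recip, self, total (kT) and an overlap
#'   flag.
#' @export
ewald_energy <- function(config, alpha = NULL, kmax2 = NULL, nshell = 0) {
  L <- config$L
  if (is.null(alpha)) alpha <- 5.6 / L
  if (is.null(kmax2)) kmax2 <- .ewald_kmax2(alpha, L)
  mc_total_energy(config$x, config$y, config$z, config$q, config$rad,
                  L, .cfg_lambda(config), alpha, as.integer(kmax2),
                  as.integer(nshell))
}

.cfg_lambda <- function(config) {
  if (!is.null(config$spec)) config$spec$lambda_B else config$lambda_B
}

## reciprocal cutoff giving ~1e-7 truncation at splitting parameter alpha
.ewald_kmax2 <- function(alpha, L) {
  nmax <- ceiling(alpha * L / pi * sqrt(16.2))
  as.integer(nmax^2)
}

#' Run Metropolis sweeps on a configuration
#'
#' One sweep = one attempted random translation per mobile particle; hard
#' overlaps always reject; acceptance by min(1, exp(-dU)).
#'
#' @param config An \code{sdl_mcconfig}.
#' @param sweeps Number of sweeps.
#' @param displacement Maximum displacement amplitude (nm) per Cartesian
#'   component.
#' @param alpha,kmax2 Ewald controls (defaults as in
#'   \code{\link{ewald_energy}}).
#' @param sample_every If > 0, bin the configuration every so many sweeps.
#' @param bin_width Spherical bin width (nm) for sampling.
#' @return List with the updated config, acceptance fraction, bin counts and
#'   the running/fresh total energies (bookkeeping check).
#' @export
metropolis_sweeps <- function(config, sweeps, displacement,
                              alpha = NULL, kmax2 = NULL,
                              sample_every = 0, bin_width = NULL) {
  L <- config$L
  if (is.null(alpha)) alpha <- 4.5 / L
  if (is.null(kmax2)) kmax2 <- .ewald_kmax2(alpha, L)
  R <- config$rad[1]
  if (is.null(bin_width)) bin_width <- min(config$rad[config$mobile]) / 5
  nbins <- max(1L, floor((L / 2 - R) / bin_width))
  nsp <- max(config$spc) + 1L
  res <- mc_run(config$x, config$y, config$z, config$q, config$rad,
                config$spc, config$mobile, L, .cfg_lambda(config),
                alpha, as.integer(kmax2), displacement,
                as.integer(sweeps), as.integer(sample_every),
                R, bin_width, as.integer(nbins), as.integer(nsp), L / 2)
  config$x <- res$x; config$y <- res$y; config$z <- res$z
  list(config = config,
       acceptance = if (res$attempted > 0) res$accepted / res$attempted else 1,
       counts = res$counts, nsamples = res$nsamples,
       bin_r0 = R, bin_width = bin_width, nbins = nbins,
       U_running = res$U_running, U_fresh = res$U_fresh)
}

#' Convert bin counts to density profiles
#'
#' Exact shell volumes (4 pi/3)(r_{k+1}^3 - r_k^3); densities in nm^-3.
#'
#' @param counts Matrix (nbins x nspecies) of accumulated counts.
#' @param nsamples Number of configurations sampled.
#' @param bin_r0 Inner edge of the first bin (nm).
#' @param bin_width Bin width (nm).
#' @return List with bin centers \code{r} and density matrix \code{rho}.
#' @export
bin_density_profiles <- function(counts, nsamples, bin_r0, bin_width) {
  nb <- nrow(counts)
  edges <- bin_r0 + bin_width * (0:nb)
  vol <- 4 * pi / 3 * diff(edges^3)
  list(r = (edges[-1] + edges[-(nb + 1)]) / 2,
       rho = counts / (vol * max(nsamples, 1)))
}

#' Run a full canonical Monte Carlo simulation
#'
#' Equilibration with displacement auto-tuning towards the target acceptance
#' window, then production split into blocks; per-block spherical-bin density
#' profiles give means and standard errors (block averaging).  The mean
#' electrostatic potential is computed from the binned charge density with
#' the same Gauss-law quadrature as the density functional solver.
#'
#' @param spec The \code{sdl_system}.
#' @param L Box edge (nm).
#' @param seed RNG seed; the run is reproducible given the seed.
#' @param equilibration,production Sweep counts.
#' @param blocks Number of production blocks (>= 10 recommended).
#' @param sample_every Sampling stride in sweeps.
#' @param bin_width Bin width in nm (default sigma_min/10).
#' @param target_acceptance Two-sided tuning window, default c(0.35, 0.5).
#' @param displacement Initial maximum displacement (nm).
#' @param alpha,kmax2 Ewald controls.
#' @param verbose Print block progress.
#' @return An object of class \code{sdl_mcreport}: binned profiles with
#'   standard errors, psi(r) with errors, acceptance rate, energy bookkeeping
#'   drift, schedule and seed.
#' @export
run_simulation <- function(spec, L, seed = 1, equilibration = 2e4,
                           production = 1e5, blocks = 10,
                           sample_every = 10, bin_width = NULL,
                           target_acceptance = c(0.35, 0.5),
                           displacement = NULL, alpha = NULL, kmax2 = NULL,
                           verbose = FALSE) {
  stopifnot(blocks >= 1)
  sig <- sp_sigma(spec)
  if (is.null(bin_width)) bin_width <- min(sig[sp_density(spec) > 0]) / 10
  ## start the displacement at a scale the tuner can reach quickly from
  ## either side (hard liquids want ~sigma/2, dilute systems much more)
  if (is.null(displacement)) displacement <- max(min(sig) / 2, L / 50)
  cfg <- build_initial_configuration(spec, L, seed)
  ## equilibrate in chunks, tuning the displacement
  ntune <- 20
  chunk <- max(1, floor(equilibration / ntune))
  acc <- NA_real_
  for (k in seq_len(ntune)) {
    st <- metropolis_sweeps(cfg, chunk, displacement, alpha, kmax2)
    cfg <- st$config; acc <- st$acceptance
    if (acc < target_acceptance[1])
      displacement <- displacement * if (acc < 0.1) 0.5 else 0.8
    else if (acc > target_acceptance[2])
      displacement <- min(displacement * if (acc > 0.8) 2 else 1.25, L / 4)
    if (verbose)
      message(sprintf("equil chunk %d: acc %.3f, disp %.4f", k, acc,
                      displacement))
  }
  ## production blocks with frozen displacement
  bsweeps <- max(1, floor(production / blocks))
  block_rho <- NULL
  acc_prod <- 0; drift <- 0
  psi_blocks <- NULL
  for (b in seq_len(blocks)) {
    st <- metropolis_sweeps(cfg, bsweeps, displacement, alpha, kmax2,
                            sample_every = sample_every,
                            bin_width = bin_width)
    cfg <- st$config
    acc_prod <- acc_prod + st$acceptance / blocks
    drift <- max(drift, abs(st$U_running - st$U_fresh) /
                   max(abs(st$U_fresh), 1))
    pr <- bin_density_profiles(st$counts, st$nsamples, st$bin_r0,
                               st$bin_width)
    if (is.null(block_rho))
      block_rho <- array(0, c(length(pr$r), ncol(pr$rho), blocks))
    block_rho[, , b] <- pr$rho
    psi_blocks <- cbind(psi_blocks,
                        .psi_from_bins(pr, spec, cfg$Z_M))
    if (verbose) message(sprintf("block %d/%d: acc %.3f", b, blocks,
                                 st$acceptance))
  }
  pr <- bin_density_profiles(st$counts, 1, st$bin_r0, st$bin_width)  # grid only
  rho_mean <- apply(block_rho, c(1, 2), mean)
  rho_se <- apply(block_rho, c(1, 2), stats::sd) / sqrt(blocks)
  psi_mean <- rowMeans(psi_blocks)
  psi_se <- apply(psi_blocks, 1, stats::sd) / sqrt(blocks)
  if (production > 0 && (acc_prod < 0.01 || acc_prod > 0.99))
    warning("production acceptance ", signif(acc_prod, 3),
            " outside [1%, 99%]")
  structure(list(
    r = pr$r, rho = rho_mean, rho_se = rho_se,
    psi = psi_mean, psi_se = psi_se,
    acceptance = acc_prod, displacement = displacement,
    energy_drift = drift, blocks = blocks,
    equilibration = equilibration, production = production,
    sample_every = sample_every, bin_width = bin_width,
    seed = seed, L = L, Z_M = cfg$Z_M, counts = cfg$counts,
    config = cfg, spec = spec, model = "mc"
  ), class = "sdl_mcreport")
}

## MEP from binned densities: same two-term Gauss-law quadrature as the DFT,
## on the bin-center grid, with the (integer) macroion valence
.psi_from_bins <- function(pr, spec, ZM) {
  z <- sp_valence(spec); lam <- spec$lambda_B
  r <- pr$r
  q <- as.numeric(pr$rho %*% z)
  I1 <- .cumtrapz(r, r^2 * q)
  I2c <- .cumtrapz(r, r * q)
  I2 <- I2c[length(I2c)] - I2c
  psi <- lam * ZM / r + 4 * pi * lam * (I1 / r + I2)
  psi - psi[length(psi)]
}

#' @export
print.sdl_mcreport <- function(x, ...) {
  cat(sprintf(
    "MC report: L = %g nm, %d+%d sweeps (%d blocks), seed %d\n",
    x$L, x$equilibration, x$production, x$blocks, x$seed))
  cat(sprintf("  particles: %s; Z_M = %d\n",
              paste(names(x$counts), x$counts, collapse = ", "), x$Z_M))
  cat(sprintf("  acceptance %.3f, displacement %.4f nm, energy drift %.2e\n",
              x$acceptance, x$displacement, x$energy_drift))
  invisible(x)
}
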