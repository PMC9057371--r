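test_that("spherical convolution is exact for constants and thin shells", {
  r_in <- seq(0.2, 6, by = 0.02)
  r_out <- seq(1, 5, by = 0.02)
  ## normalized unit-ball kernel maps constants to themselves
  K <- function(s) ifelse(s <= 0.5, 1 / (4 * pi / 3 * 0.5^3), 0)
  out <- spherical_convolution(rep(2.5, length(r_in)), K, 0.5, r_out, r_in,
                               normalize = TRUE)
  expect_equal(out, rep(2.5, length(r_out)), tolerance = 1e-12)
  ## narrow shell against the unit-ball kernel: closed-form shell average
  r0 <- 3; w <- 0.04
  f <- exp(-(r_in - r0)^2 / (2 * w^2)) / (sqrt(2 * pi) * w)  # ~ delta(r - r0)
  got <- spherical_convolution(f, K, 0.5, r_out, r_in, normalize = TRUE)
  ## analytic: (f*K)(r) = shell-ball overlap volume fraction / (4pi r0^2 ...)
  a <- 0.5
  shell_ball <- function(rr) {
    out <- numeric(length(rr))
    out[abs(rr - r0) < a] <- pi * r0 *
      (a^2 - (rr[abs(rr - r0) < a] - r0)^2) / rr[abs(rr - r0) < a]
    out
  }
  oracle <- shell_ball(r_out) / (4 * pi / 3 * a^3)
  ## compare away from the overlap-window kinks, which the finite shell
  ## width smears at first order in w
  m <- abs(abs(r_out - r0) - a) > 3 * w
  expect_lt(max(abs(got - oracle)[m]), 0.01 * max(oracle))
})

test_that("spherical convolution matches brute-force 3D quadrature", {
  set.seed(21)
  r_in <- seq(0.2, 5, by = 0.025)
  f <- 1 + 0.5 * sin(2 * r_in) * exp(-(r_in - 2)^2)
  a <- 0.45
  K <- function(s) ifelse(s <= a, 1 - (s / a)^2, 0)   # smooth compact kernel
  r_out <- c(1.3, 2.0, 2.9)
  got <- spherical_convolution(f, K, a, r_out, r_in)
  fanal <- stats::approxfun(r_in, f, rule = 2)
  for (k in seq_along(r_out)) {
    npt <- 3e5
    u <- matrix(rnorm(3 * npt), ncol = 3); u <- u / sqrt(rowSums(u^2))
    rad <- a * runif(npt)^(1 / 3)
    pts <- u * rad
    pts[, 1] <- pts[, 1] + r_out[k]
    mc <- mean(fanal(sqrt(rowSums(pts^2))) * K(rad)) * (4 * pi / 3 * a^3)
    expect_equal(got[k], mc, tolerance = 0.01)
  }
})

test_that("mean electrostatic potential has the exact degenerate limits", {
  sp <- fx_dilute()
  g <- radial_grid(1.5, 6, 0.01)
  ## no ions: bare Coulomb, shifted to zero at rmax
  prof0 <- list(grid = g, rho = matrix(0, g$n, 2))
  psi0 <- mep_from_profiles(prof0, sp)
  expect_equal(psi0, sp$lambda_B * 1 * (1 / g$r - 1 / g$rmax),
               tolerance = 1e-12)
  ## all charges zero
  sp0 <- system_spec(list(species("s", 0.3, 0, 5)), macroion(1.5, Z_M = 0))
  profz <- list(grid = g, rho = matrix(5 * 0.60221, g$n, 1))
  expect_true(all(mep_from_profiles(profz, sp0) == 0))
  ## counter-charge in a thin shell: spherical capacitor inside, zero outside
  shell <- synthetic_profile("shell", sp, g, list(r0 = 3, width = 0.05))
  psi <- shell$psi
  expect_lt(max(abs(psi[g$r > 3.2])), 1e-3)
  expect_equal(psi[1], sp$lambda_B * 1 * (1 / 1.5 - 1 / 3), tolerance = 1e-2)
})

test_that("perturbative electrostatic term vanishes for uniform profiles", {
  sp <- fx_restricted()
  g <- radial_grid(1.5, 3.5, 0.02)
  rho_b <- sapply(sp$species, function(s) s$density)
  prof <- list(grid = g, rho = matrix(rho_b, g$n, 2, byrow = TRUE))
  ce <- c1_el_profile(prof, sp)
  interior <- g$r > g$R + 0.5 & g$r < g$rmax - 0.5
  expect_lt(max(abs(ce[interior, ])), 1e-12)
})

test_that("single-species bump in the el convolution matches brute force", {
  sp <- fx_restricted()
  pp <- solve_msa_gamma(sp)
  g <- radial_grid(1.5, 3.5, 0.02)
  rho_b <- sapply(sp$species, function(s) s$density)
  rho <- matrix(rho_b, g$n, 2, byrow = TRUE)
  rho[, 1] <- rho[, 1] * (1 + 0.4 * exp(-(g$r - 2.2)^2 / 0.05))
  prof <- list(grid = g, rho = rho)
  ce <- c1_el_profile(prof, sp, pp)
  ## oracle: direct Monte Carlo quadrature of the short-range residual kernel
  lam <- sp$lambda_B
  Ksr <- function(s) {
    v <- msa_el_dcf(pp, sp, 2, 1, s) + ifelse(s > 0 & s < 0.4,
                                              lam * 1 * (-1) / s, 0)
    v[s >= 0.4] <- 0
    v
  }
  drho1 <- stats::approxfun(g$r, rho[, 1] - rho_b[1], yleft = -rho_b[1],
                            yright = 0)
  set.seed(31)
  for (r0 in c(2.0, 2.4)) {
    npt <- 3e5
    u <- matrix(rnorm(3 * npt), ncol = 3); u <- u / sqrt(rowSums(u^2))
    rad <- 0.4 * runif(npt)^(1 / 3)
    pts <- u * rad
    pts[, 1] <- pts[, 1] + r0
    mc <- mean(drho1(sqrt(rowSums(pts^2))) * Ksr(rad)) * (4 * pi / 3 * 0.4^3)
    got <- ce[which.min(abs(g$r - r0)), 2]
    expect_lt(abs(got - mc), 0.03 * abs(mc))
  }
})

test_that("uncharged system converges to a pure packing profile", {
  sp <- system_spec(list(species("s", 0.31875, 0, 8)), macroion(1.0, Z_M = 0))
  prof <- solve_dft(sp, radial_grid(1.0, 3.5, 0.31875 / 25))
  expect_true(prof$converged)
  expect_true(all(prof$psi == 0))
  rho_b <- sp$species[[1]]$density
  ## bulk recovery at the outer edge and an enhanced contact value
  expect_lt(abs(prof$rho[prof$grid$n, 1] / rho_b - 1), 1e-4)
  contact <- which(prof$grid$r >= 1.0 + 0.31875 / 2)[1]
  expect_gt(prof$rho[contact, 1], rho_b)
})

test_that("converged desk-scale profiles satisfy Poisson and bulk recovery", {
  prof <- desk_dft()
  sp <- prof$spec
  expect_true(prof$converged)
  r <- prof$grid$r; h <- prof$grid$h
  z <- sapply(sp$species, function(s) s$valence)
  q <- as.numeric(prof$rho %*% z)
  ## discrete Poisson: (1/r)(r psi)'' = -4 pi lam q
  rp <- r * prof$psi
  i <- 2:(length(r) - 1)
  lhs <- (rp[i + 1] - 2 * rp[i] + rp[i - 1]) / h^2 / r[i]
  rhs <- -4 * pi * sp$lambda_B * q[i]
  expect_lt(max(abs(lhs - rhs)), 1e-6 * max(abs(rhs)))
  ## bulk recovery at the truncation radius
  rho_b <- sapply(sp$species, function(s) s$density)
  expect_lt(max(abs(prof$rho[prof$grid$n, ] / rho_b - 1)), 1e-4)
  ## Debye tail: log(r psi) linear in r with slope -kappa, fitted over the
  ## screened zone away from both the surface and the forced zero at rmax
  kap <- debye_kappa(sp)
  win <- r > prof$grid$rmax - 1.6 & r < prof$grid$rmax - 0.6
  fit <- stats::lm(log(r[win] * prof$psi[win]) ~ r[win])
  expect_equal(unname(stats::coef(fit)[2]), -kap, tolerance = 0.15)
  expect_gt(summary(fit)$r.squared, 0.999)
})
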