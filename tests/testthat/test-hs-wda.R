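test_that("uniform hard-sphere c1 matches scaled-particle thermodynamics", {
  expect_equal(uniform_c1_hs(c(0, 0), c(0.3, 0.5)), c(0, 0))
  ## one-component oracle: SPT excess chemical potential at eta = 0.3
  eta <- 0.3; rho <- 6 * eta / pi
  mu_spt <- -log(1 - eta) + 7 * eta / (1 - eta) +
    15 / 2 * eta^2 / (1 - eta)^2 + 3 * eta^3 / (1 - eta)^3
  expect_equal(-uniform_c1_hs(rho, 1.0), mu_spt, tolerance = 1e-12)
  expect_error(uniform_c1_hs(10, 1.0), "packing")
})

test_that("pair/one-particle consistency: d c1_i/d rho_j equals the kernel integral", {
  set.seed(11)
  rho <- c(0.15, 0.08); sig <- c(0.5, 0.9)
  dmat <- spheredl:::dc1_hs_drho(rho, sig)
  ## numeric differentiation of c1 vs 3D quadrature of c2, every pair
  h <- 1e-6
  ## the kernel quadrature converges first order (endpoint discontinuity);
  ## two resolutions plus Richardson extrapolation reach 1e-6
  kquad <- function(i, j, n) {
    s <- seq(0, (sig[i] + sig[j]) / 2, length.out = n)
    sum(4 * pi * s^2 * py_hs_dcf(rho, sig, i, j, s)) * (s[2] - s[1])
  }
  for (i in 1:2) for (j in 1:2) {
    rp <- rho; rp[j] <- rp[j] + h
    rm <- rho; rm[j] <- rm[j] - h
    num <- (uniform_c1_hs(rp, sig)[i] - uniform_c1_hs(rm, sig)[i]) / (2 * h)
    quad <- (4 * kquad(i, j, 80001) - kquad(i, j, 20001)) / 3
    expect_equal(num, dmat[i, j], tolerance = 1e-6)
    expect_equal(quad, dmat[i, j], tolerance = 1e-6)
  }
})

test_that("DA weights are normalized and have the correct dilute limit", {
  set.seed(5)
  for (k in 1:8) {
    rho <- runif(3, 0.01, 0.25); sig <- runif(3, 0.2, 0.6)
    i <- sample(3, 1); j <- sample(3, 1)
    reach <- (sig[i] + sig[j]) / 2
    nq <- function(n) {
      s <- seq(0, reach, length.out = n)
      sum(4 * pi * s^2 * weight_kernel(i, j, s, rho, sig)) * (s[2] - s[1])
    }
    nrm <- (4 * nq(32001) - nq(8001)) / 3   # first-order Richardson
    expect_equal(nrm, 1, tolerance = 1e-6)
  }
  ## zero-density limit: uniform over the contact sphere
  w0 <- weight_kernel(1, 2, c(0.1, 0.3, 0.5), c(0, 0), c(0.3, 0.5))
  vol <- 4 * pi / 3 * 0.4^3
  expect_equal(w0, c(1 / vol, 1 / vol, 0))
})

test_that("weighted densities preserve uniform fluids exactly", {
  sp <- model_fixture("base")
  g <- radial_grid(1.5, 3.0, 0.2125 / 10)
  rho_b <- sapply(sp$species, function(s) s$density)
  prof <- list(grid = g, rho = matrix(rho_b, g$n, 4, byrow = TRUE))
  f <- weighted_density_profile(prof, sp)
  interior <- g$r > g$R + 0.5 & g$r < g$rmax - 0.5
  for (a in 1:4) for (b in 1:4)
    expect_lt(max(abs(f$rhobar[interior, a, b] / rho_b[b] - 1)), 1e-10)
  ## and the c1 field equals the uniform value there
  c1 <- c1_hs_profile(f, sp)
  c1b <- uniform_c1_hs(rho_b, sapply(sp$species, function(s) s$diameter))
  expect_lt(max(abs(sweep(c1[interior, ], 2, c1b))), 1e-8)
})

test_that("smoothed step profile is bounded and matches brute-force quadrature", {
  sp <- system_spec(list(species("s", 0.4, 0, 5)), macroion(1.0, Z_M = 0))
  g <- radial_grid(1.0, 3.0, 0.02)
  rho_b <- sp$species[[1]]$density
  step <- ifelse(g$r < 1.8, 0.5 * rho_b, rho_b)
  prof <- list(grid = g, rho = matrix(step, ncol = 1))
  f <- weighted_density_profile(prof, sp)
  interior <- g$r > 1.5 & g$r < 2.4
  expect_true(all(f$rhobar[interior, 1, 1] >= 0.5 * rho_b - 1e-9))
  expect_true(all(f$rhobar[interior, 1, 1] <= rho_b + 1e-9))
  ## independent oracle: 3D Monte Carlo quadrature of the same convolution
  ## at two output radii
  set.seed(99)
  sig <- 0.4
  rho_ext <- function(r) ifelse(r < 1.0, 0,
                                ifelse(r < 1.8, 0.5 * rho_b,
                                       rho_b))
  for (r0 in c(1.75, 1.9)) {
    npt <- 2e5
    u <- matrix(rnorm(3 * npt), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    rad <- sig * runif(npt)^(1 / 3)  # uniform in the contact ball
    pts <- u * rad
    pts[, 1] <- pts[, 1] + r0
    rr <- sqrt(rowSums(pts^2))
    wv <- weight_kernel(1, 1, rad, rho_b, sig)
    mc <- mean(rho_ext(rr) * wv) * (4 * pi / 3 * sig^3)
    got <- f$rhobar[which.min(abs(g$r - r0)), 1, 1]
    expect_equal(got, mc, tolerance = 0.01)
  }
})

test_that("self-consistent and bulk-weight modes agree to first order", {
  sp <- system_spec(list(species("s", 0.4, 0, 3)), macroion(1.0, Z_M = 0))
  g <- radial_grid(1.0, 2.2, 0.05)
  rho_b <- sp$species[[1]]$density
  ## compare away from the hard wall, where the input really is bulk plus a
  ## small perturbation (the wall region differs at zeroth order by design)
  interior <- g$r > 1.5 & g$r < 1.9
  devs <- sapply(c(1e-3, 5e-4), function(eps) {
    pert <- rho_b * (1 + eps * sin(3 * g$r))
    prof <- list(grid = g, rho = matrix(pert, ncol = 1))
    f1 <- weighted_density_profile(prof, sp, mode = "bulk_weights")
    f2 <- weighted_density_profile(prof, sp, mode = "self_consistent")
    max(abs(f1$rhobar[interior, , ] - f2$rhobar[interior, , ])) / rho_b
  })
  ## difference is O(delta rho^2): halving the perturbation cuts it ~4x
  expect_lt(devs[2], devs[1] / 2.5)
  expect_lt(devs[1], 1e-4)
})

test_that("uniform c1 is monotone decreasing in total density", {
  scale <- seq(0.2, 1.4, by = 0.2)
  vals <- sapply(scale, function(s) uniform_c1_hs(s * c(0.1, 0.2), c(0.4, 0.6)))
  expect_true(all(diff(vals[1, ]) < 0))
  expect_true(all(diff(vals[2, ]) < 0))
})
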