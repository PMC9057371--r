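test_that("Debye screening parameter matches closed-form arithmetic", {
  sp0 <- system_spec(list(species("s", 0.3, 0, 10)), macroion(1, Z_M = 0))
  expect_identical(debye_kappa(sp0), 0)
  sp1 <- system_spec(list(species("Na", 0.3, 1, 1), species("Cl", 0.3, -1, 1)),
                     macroion(1, Z_M = 1))
  expect_equal(debye_kappa(sp1),
               sqrt(4 * pi * sp1$lambda_B * 2 * 0.60221), tolerance = 1e-4)
  expect_equal(debye_kappa(model_fixture("base")), 5.20, tolerance = 2e-3)
})

test_that("Blum closure reproduces the restricted closed form and its limits", {
  sp <- fx_restricted()
  pp <- solve_msa_gamma(sp)
  kap <- debye_kappa(sp)
  Gc <- (sqrt(1 + 2 * kap * 0.4) - 1) / (2 * 0.4)
  expect_equal(pp$gamma, Gc, tolerance = 1e-12)
  expect_equal(pp$p_n, 0)            # symmetric equal-size: no P_n
  ## point-ion limit Gamma -> kappa/2
  spp <- system_spec(list(species("Na", 1e-8, 1, 0.01),
                          species("Cl", 1e-8, -1, 0.01)), macroion(1, Z_M = 1))
  gp <- solve_msa_gamma(spp)
  expect_equal(gp$gamma, debye_kappa(spp) / 2, tolerance = 1e-7)
  ## asymmetric mixture: strictly below the point-ion bound
  pb <- solve_msa_gamma(model_fixture("base"))
  expect_lt(pb$gamma, debye_kappa(model_fixture("base")) / 2)
  ## uncharged system degrades gracefully
  g0 <- solve_msa_gamma(system_spec(list(species("s", 0.3, 0, 10)),
                                    macroion(1, Z_M = 0)))
  expect_identical(g0$gamma, 0)
})

test_that("Gamma is non-increasing when any diameter grows", {
  sig2 <- seq(0.1, 0.8, by = 0.1)
  gam <- sapply(sig2, function(s2) {
    sp <- system_spec(list(species("A", 0.2, 2, 0.1),
                           species("B", s2, -1, 0.2)), macroion(1, Z_M = 1))
    solve_msa_gamma(sp)$gamma
  })
  expect_true(all(diff(gam) < 0))
})

test_that("PY mixture DCF has the exact one-component and low-density limits", {
  s <- seq(0, 1.5, length.out = 400)
  expect_true(all(py_hs_dcf(0.7, 1.0, 1, 1, s[s > 1]) == 0))
  ## low-density limit: c -> -1 inside the core
  expect_equal(py_hs_dcf(c(1e-12, 1e-12), c(0.5, 1.0), 1, 2, 0.3), -1,
               tolerance = 1e-10)
  ## one-component closed form at eta = 0.3
  eta <- 0.3; rho <- 6 * eta / pi
  l1 <- (1 + 2 * eta)^2 / (1 - eta)^4
  l2 <- -(1 + eta / 2)^2 / (1 - eta)^4
  sc <- seq(1e-3, 0.999, length.out = 200)
  oracle <- -(l1 + 6 * eta * l2 * sc + eta * l1 / 2 * sc^3)
  expect_equal(py_hs_dcf(rho, 1.0, 1, 1, sc), oracle, tolerance = 1e-10)
  ## the origin is evaluated via a tiny-separation limit (1/s cancellation)
  expect_equal(py_hs_dcf(rho, 1.0, 1, 1, 0), -l1, tolerance = 1e-6)
  ## symmetry for random mixtures
  set.seed(3)
  for (k in 1:5) {
    rho <- runif(3, 0, 0.3); sig <- runif(3, 0.2, 0.6)
    ss <- seq(0, 0.7, length.out = 50)
    for (i in 1:3) for (j in 1:3)
      expect_equal(py_hs_dcf(rho, sig, i, j, ss),
                   py_hs_dcf(rho, sig, j, i, ss), tolerance = 1e-13)
  }
})

test_that("electrostatic DCF: exact tail, restricted-case oracle, symmetry", {
  sp <- fx_restricted()
  pp <- solve_msa_gamma(sp)
  lam <- sp$lambda_B; G <- pp$gamma
  ## exact -lam z_i z_j / s beyond contact (machine precision)
  s_out <- c(0.4, 0.5, 0.8, 2.0)
  expect_equal(msa_el_dcf(pp, sp, 1, 2, s_out), lam / s_out,
               tolerance = 1e-14)
  expect_equal(msa_el_dcf(pp, sp, 1, 1, s_out), -lam / s_out,
               tolerance = 1e-14)
  ## inside the core: Waisman-Lebowitz closed form in Gamma
  s_in <- seq(0.02, 0.38, by = 0.01)
  wl <- lam * (2 * G / (1 + G * 0.4) - G^2 * s_in / (1 + G * 0.4)^2)
  got <- msa_el_dcf(pp, sp, 1, 2, s_in)
  expect_lt(max(abs(got - wl)) / max(abs(wl)), 0.01)
  ## the el DCF is discontinuous at contact: the inside limit equals the
  ## closed-form value, not the -lam zz/s tail
  inside_contact <- lam * G * (2 + G * 0.4) / (1 + G * 0.4)^2
  expect_equal(msa_el_dcf(pp, sp, 1, 2, 0.3999), inside_contact,
               tolerance = 2e-2)
  expect_gt(abs(inside_contact - lam / 0.4), 0.1)  # a genuine jump
  ## symmetry in the pair indices
  expect_equal(msa_el_dcf(pp, sp, 1, 2, s_in), msa_el_dcf(pp, sp, 2, 1, s_in),
               tolerance = 1e-12)
})

test_that("uncharged systems have identically zero electrostatic kernels", {
  sp <- system_spec(list(species("s", 0.3, 0, 10)), macroion(1, Z_M = 0))
  pp <- solve_msa_gamma(sp)
  s <- seq(0, 1, length.out = 30)
  expect_true(all(msa_el_dcf(pp, sp, 1, 1, s) == 0))
})

test_that("kernel dump writes a parseable two-part table", {
  sp <- fx_restricted()
  f <- tempfile(fileext = ".txt")
  dump_dcf_kernels(sp, 1, 2, seq(0.01, 0.8, by = 0.01), f)
  tab <- utils::read.table(f, skip = 2)
  expect_equal(ncol(tab), 3)
  expect_true(all(tab[tab[, 1] > 0.4, 2] == 0))  # hs part zero beyond contact
  unlink(f)
})
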