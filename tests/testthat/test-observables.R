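test_that("integrated charge starts at Z_M and tracks constructed charge", {
  sp <- fx_dilute()
  g <- radial_grid(1.5, 8, 0.01)
  ## uniform neutral ionic soup: P(r) = Z_M everywhere
  uni <- synthetic_profile("uniform", sp, g)
  P <- integrated_charge(uni, sp)
  expect_equal(P[1], 1)
  expect_equal(P, rep(1, length(P)), tolerance = 1e-12)
  expect_equal(integrated_ionic_charge(uni, sp), rep(0, length(P)),
               tolerance = 1e-12)
  ## countercharge concentrated in a shell at r0: P vanishes beyond it
  sh <- synthetic_profile("shell", sp, g, list(r0 = 3, width = 0.06))
  Ps <- integrated_charge(sh, sp)
  expect_equal(Ps[1], 1)
  expect_lt(max(abs(Ps[g$r > 3.3])), 1e-6)
})

test_that("charge-state classification flags CR and amplification correctly", {
  r <- seq(1, 5, by = 0.01)
  ZM <- 10
  ## monotone decay: nothing flagged
  cls <- classify_charge_state(ZM * exp(-(r - 1)), r, ZM)
  expect_false(cls$cr); expect_false(cls$amplification)
  expect_equal(cls$delta_Z, 0)
  ## dip to -0.2 Z_M: charge reversal with an interpolated first crossing
  P <- ZM * cos(pi * (r - 1) / 2) * exp(-(r - 1))
  cls2 <- classify_charge_state(P, r, ZM)
  expect_true(cls2$cr)
  expect_equal(cls2$cr_radius, 2, tolerance = 1e-3)
  ## peak at 1.3 Z_M: amplification with delta_Z = 0.3 Z_M
  P3 <- ZM * (1 + 0.3 * exp(-(r - 2)^2)) * exp(-pmax(r - 3, 0))
  cls3 <- classify_charge_state(P3, r, ZM)
  expect_true(cls3$amplification)
  expect_equal(cls3$delta_Z, 0.3 * ZM, tolerance = 1e-6)
  expect_equal(cls3$amp_radius, 2, tolerance = 0.02)
  ## mirrored for a negative macroion
  cls4 <- classify_charge_state(-P3, r, -ZM)
  expect_true(cls4$amplification)
  expect_equal(cls4$delta_Z, -0.3 * ZM, tolerance = 1e-6)
  ## undefined for an uncharged macroion
  cls5 <- classify_charge_state(P, r, 0)
  expect_true(is.na(cls5$cr))
})

test_that("capacitive compactness is the ideal-capacitor shell radius", {
  sp <- fx_dilute()
  R <- 1.5; ZM <- 1
  ## all countercharge in a shell at R + delta: tau_c = R + delta exactly
  for (delta in c(0.3, 1.0, 2.5)) {
    psi0 <- sp$lambda_B * ZM * (1 / R - 1 / (R + delta))
    expect_equal(capacitive_compactness(psi0, ZM, R, sp), R + delta,
                 tolerance = 1e-12)
  }
  ## perfect screening at contact: tau_c -> R
  expect_equal(capacitive_compactness(0, ZM, R, sp), R)
  ## algebraic roundtrip through a numerically inverted capacitor
  psi0 <- dh_potential(ZM, R, R, sp)
  tau <- capacitive_compactness(psi0, ZM, R, sp)
  inv <- uniroot(function(t) sp$lambda_B * ZM * (1 / R - 1 / t) - psi0,
                 c(R + 1e-9, 1e6), tol = 1e-14)$root
  expect_equal(tau, inv, tolerance = 1e-10)
  ## no screening: flagged infinite
  expect_warning(ti <- capacitive_compactness(sp$lambda_B * ZM / R, ZM, R, sp),
                 "no screening")
  expect_identical(ti, Inf)
})

test_that("observable sets assemble consistently from synthetic profiles", {
  sp <- fx_dilute()
  g <- radial_grid(1.5, 14, 0.02)
  sh <- synthetic_profile("shell", sp, g, list(r0 = 3, width = 0.06))
  ob <- observable_set(sh, sp)
  expect_equal(ob$tau_c, 3, tolerance = 0.02)   # the shell radius
  expect_equal(ob$Z_M, 1)
  expect_false(ob$amplification)
  ## exponential screening reproduces the linearized potential
  es <- synthetic_profile("exponential_screening", sp, g)
  kap <- debye_kappa(sp)
  m <- g$r < 1.5 + 3 / kap
  dh <- dh_potential(1, 1.5, g$r[m], sp)
  expect_lt(max(abs(es$psi[m] - dh)), 0.03 * max(dh))
})
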