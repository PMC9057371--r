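test_that("initial configurations have exact counts, neutrality, determinism", {
  sp <- model_fixture("base")
  suppressWarnings(cfg <- build_initial_configuration(sp, L = 6, seed = 4))
  ## counts from the reference concentrations in a 216 nm^3 cell
  expect_equal(unname(cfg$counts["Na"]), 130)
  expect_equal(unname(cfg$counts["Mg"]), 65)
  expect_equal(unname(cfg$counts["Cl"]), 130 + 130 + 18)
  expect_identical(sum(cfg$q), 0)         # exact cell neutrality with Z_M
  suppressWarnings(cfg2 <- build_initial_configuration(sp, L = 6, seed = 4))
  expect_identical(cfg$x, cfg2$x)         # deterministic given the seed
  ## no overlaps in the inserted configuration
  E <- ewald_energy(cfg)
  expect_false(E$overlap)
  ## pure salt, uncharged macroion: equal counter/co counts
  sp0 <- system_spec(list(species("Na", 0.3, 1, 0.2),
                          species("Cl", 0.3, -1, 0.2)), macroion(0.5, Z_M = 0))
  cfg0 <- suppressWarnings(build_initial_configuration(sp0, 4, seed = 1))
  expect_equal(unname(cfg0$counts["Na"]), unname(cfg0$counts["Cl"]))
})

test_that("Ewald energy reproduces the rock-salt Madelung constant", {
  d <- 0.3; L <- 2 * d; lam <- 0.714
  g <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  cfg <- list(L = L, x = g$x * d + d / 4, y = g$y * d + d / 4,
              z = g$z * d + d / 4, q = (-1)^(g$x + g$y + g$z),
              rad = rep(0.01, 8), lambda_B = lam)
  E <- ewald_energy(cfg, alpha = 6 / L, nshell = 2)
  ## Madelung energy per ion pair (4 NaCl formula units in the cell)
  expect_equal(E$total / 4, -1.747565 * lam / d, tolerance = 1e-5)
  ## independence of the splitting parameter
  vals <- sapply(c(4, 5.5, 7, 8) / L, function(al)
    ewald_energy(cfg, alpha = al, nshell = ceiling(6 / (al * L)) + 1)$total)
  expect_lt(diff(range(vals)) / abs(mean(vals)), 1e-6)
  ## doubling the reciprocal cutoff changes nothing at this alpha
  E2 <- ewald_energy(cfg, alpha = 6 / L, nshell = 2,
                     kmax2 = 4 * spheredl:::.ewald_kmax2(6 / L, L))
  expect_lt(abs(E2$total - E$total) / abs(E$total), 1e-6)
  ## all charges zero
  cfg$q <- rep(0, 8)
  expect_identical(ewald_energy(cfg)$total, 0)
  ## two opposite charges far apart in a large cell: direct Coulomb
  cfg2 <- list(L = 60, x = c(20, 23), y = c(20, 20), z = c(20, 20),
               q = c(1, -1), rad = c(0.1, 0.1), lambda_B = lam)
  expect_equal(ewald_energy(cfg2, alpha = 0.1, nshell = 1)$total,
               -lam / 3, tolerance = 1e-3)
})

test_that("Metropolis sweeps conserve energy bookkeeping and accept trivially", {
  sp <- fx_desk()
  suppressWarnings(cfg <- build_initial_configuration(sp, 4, seed = 9))
  ## zero displacement: all moves accepted, state unchanged
  st <- metropolis_sweeps(cfg, 5, displacement = 0)
  expect_equal(st$acceptance, 1)
  expect_identical(st$config$x, cfg$x)
  ## running energy equals a fresh recompute after real sweeps
  st2 <- metropolis_sweeps(cfg, 400, displacement = 0.12)
  expect_lt(abs(st2$U_running - st2$U_fresh) / max(abs(st2$U_fresh), 1), 1e-8)
  ## ideal system (pointlike, uncharged): every move accepted
  spi <- system_spec(list(species("id", 1e-4, 0, 2)), macroion(1e-6, Z_M = 0),
                     check = FALSE)
  cfgi <- suppressWarnings(build_initial_configuration(spi, 3, seed = 2))
  sti <- metropolis_sweeps(cfgi, 20, displacement = 0.5)
  expect_equal(sti$acceptance, 1)
})

test_that("spherical binning conserves counts and recovers flat profiles", {
  ## ideal gas around a small hard macroion: flat profile beyond contact
  spi <- system_spec(list(species("id", 1e-3, 0, 3)), macroion(0.4, Z_M = 0),
                     check = FALSE)
  rep <- suppressWarnings(
    run_simulation(spi, L = 3.4, seed = 5, equilibration = 200,
                   production = 3000, blocks = 10, sample_every = 3,
                   bin_width = 0.1))
  ## reference: exact accessible-volume average (quantized counts, and the
  ## macroion excludes a small central volume)
  rho_ref <- sum(rep$counts) / (3.4^3 - 4 * pi / 3 * (0.4 + 5e-4)^3)
  dev <- abs(rep$rho[, 1] - rho_ref) / (3 * rep$rho_se[, 1] + 1e-9)
  expect_lt(mean(dev > 1), 0.06)      # ~3 sigma with 10-block errors
  ## bookkeeping identity: halving the bin width preserves integrated counts
  cnt <- matrix(c(4, 6, 0, 2, 8, 10), ncol = 2)
  p1 <- bin_density_profiles(cnt, 2, 1, 0.2)
  edges1 <- 1 + 0.2 * (0:3)
  vol1 <- 4 * pi / 3 * diff(edges1^3)
  expect_equal(sum(p1$rho[, 1] * vol1) * 2, sum(cnt[, 1]))
  ## single occupied bin: exact count / volume
  cnt2 <- matrix(c(0, 5, 0), ncol = 1)
  p2 <- bin_density_profiles(cnt2, 1, 2, 0.5)
  expect_equal(p2$rho[2, 1], 5 / (4 * pi / 3 * (3^3 - 2.5^3)))
})

test_that("two seeds give statistically consistent double layers", {
  sp <- system_spec(list(species("Na", 0.3, 1, 0.3),
                         species("Cl", 0.3, -1, 0.3)), macroion(0.8, Z_M = 6))
  reps <- lapply(c(13, 29), function(sd) suppressWarnings(
    run_simulation(sp, L = 3.6, seed = sd, equilibration = 1500,
                   production = 12000, blocks = 10, sample_every = 5,
                   bin_width = 0.06)))
  for (a in 1:2) {
    joint <- sqrt(reps[[1]]$rho_se[, a]^2 + reps[[2]]$rho_se[, a]^2)
    dev <- abs(reps[[1]]$rho[, a] - reps[[2]]$rho[, a]) / (3 * joint + 1e-12)
    expect_lt(mean(dev > 1), 0.08)
  }
})
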