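# shared systems and lazily cached heavy solves (one process-wide solve each)

fx_desk <- function()
  system_spec(list(species("Mg", 0.2125, 2, 0.05),
                   species("Na", 0.265625, 1, 0.1),
                   species("Cl", 0.425, -1, 0.2),
                   species("solvent", 0.31875, 0, 5)),
              macroion(1.0, Z_M = 8))

fx_restricted <- function(c = 0.5, sigma = 0.4)
  system_spec(list(species("Na", sigma, 1, c), species("Cl", sigma, -1, c)),
              macroion(1.5, Z_M = 18))

fx_dilute <- function()
  system_spec(list(species("Na", 0.2125, 1, 0.01),
                   species("Cl", 0.2125, -1, 0.01)),
              macroion(1.5, Z_M = 1))

.solve_cache <- new.env(parent = emptyenv())

cached_solve <- function(key, fn) {
  if (is.null(.solve_cache[[key]])) .solve_cache[[key]] <- fn()
  .solve_cache[[key]]
}

# base-fixture DFT at the test resolution (reused by several acceptance tests)
base_dft <- function()
  cached_solve("base_dft", function()
    solve_dft(model_fixture("base"),
              grid = radial_grid(1.5, 4.9, 0.2125 / 20)))

desk_dft <- function()
  cached_solve("desk_dft", function()
    solve_dft(fx_desk(), grid = radial_grid(1.0, 4.6, 0.2125 / 20)))
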