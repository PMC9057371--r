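## Configuration files, deterministic profile writers/readers, the registry
## of reference parameter sets, and synthetic profiles for tests.

#' Write a profile set to columnar text
#'
#' Header: provenance comments plus
#' \code{# r_nm rho_<label>... psi_kT_per_e}; one row per node, 17
#' significant digits (bit-exact double roundtrip), deterministic
#' formatting.
#'
#' @param profiles An \code{sdl_profiles} (DFT/URMGC) or \code{sdl_mcreport}.
#' @param path Output file.
#' @param spec The system (labels); taken from the object if absent.
#' @return The path, invisibly.
#' @export
write_profiles <- function(profiles, path, spec = profiles$spec) {
  labs <- sp_label(spec)
  if (inherits(profiles, "sdl_mcreport")) {
    r <- profiles$r; rho <- profiles$rho; psi <- profiles$psi
  } else {
    r <- profiles$grid$r; rho <- profiles$rho; psi <- profiles$psi
  }
  hdr <- c(sprintf("# model=%s", profiles$model),
           sprintf("# Z_M=%.10g R_nm=%.10g eps=%.10g T_K=%.10g",
                   spec$macroion$valence, spec$macroion$radius, spec$eps,
                   spec$temperature),
           if (!is.null(profiles$seed)) sprintf("# seed=%d", profiles$seed),
           paste(c("# r_nm", paste0("rho_", labs), "psi_kT_per_e"),
                 collapse = " "))
  m <- cbind(r, rho, psi)
  body <- apply(m, 1, function(row)
    paste(formatC(row, digits = 17, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a profile file written by \code{\link{write_profiles}}
#'
#' @param path File path.
#' @return List with \code{r}, \code{rho} (matrix), \code{psi}, \code{model}
#'   and the header attributes.
#' @export
read_profiles <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  model <- sub("# model=", "", hdr[grepl("^# model=", hdr)])
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  nc <- ncol(m)
  cols <- strsplit(sub("^# ", "", hdr[length(hdr)]), "\\s+")[[1]]
  list(r = m[, 1], rho = m[, 2:(nc - 1), drop = FALSE], psi = m[, nc],
       model = model, columns = cols)
}

#' Load a run configuration from a YAML file
#'
#' Schema: \code{species} (list with label, diameter_nm, valence,
#' concentration_M), \code{macroion} (R_nm plus Q_C_per_m2 and/or Z_M),
#' optional \code{epsilon} (78.5), \code{T_K} (298), and solver/schedule
#' blocks \code{dft}, \code{mc}, \code{pb}.  Unknown top-level keys are
#' rejected; if both Q and Z_M are given they must be consistent.
#'
#' @param path YAML file.
#' @return List with \code{spec} (an \code{sdl_system}) and the remaining
#'   control blocks, defaults applied.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("species", "macroion", "epsilon", "T_K", "dft", "mc", "pb",
             "observables", "output", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (is.null(cfg$species) || is.null(cfg$macroion))
    stop("config must define 'species' and 'macroion'")
  spl <- lapply(cfg$species, function(s) {
    need <- c("label", "diameter_nm", "valence", "concentration_M")
    miss <- setdiff(need, names(s))
    if (length(miss)) stop("species entry missing: ",
                           paste(miss, collapse = ", "))
    species(s$label, s$diameter_nm, s$valence, s$concentration_M)
  })
  mi <- cfg$macroion
  if (is.null(mi$R_nm)) stop("macroion needs R_nm")
  mac <- macroion(mi$R_nm, Z_M = mi$Z_M, Q = mi$Q_C_per_m2)
  spec <- system_spec(spl, mac,
                      eps = if (is.null(cfg$epsilon)) 78.5 else cfg$epsilon,
                      temperature = if (is.null(cfg$T_K)) 298 else cfg$T_K)
  list(spec = spec, dft = cfg$dft, mc = cfg$mc, pb = cfg$pb,
       observables = cfg$observables, output = cfg$output,
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}

#' Write a system specification back to YAML
#'
#' @param spec An \code{sdl_system}.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
dump_config <- function(spec, path) {
  cfg <- list(
    species = lapply(spec$species, function(s)
      list(label = s$label, diameter_nm = s$diameter, valence = s$valence,
           concentration_M = s$concentration)),
    macroion = list(R_nm = spec$macroion$radius,
                    Z_M = spec$macroion$valence,
                    Q_C_per_m2 = spec$macroion$surface_charge_density),
    epsilon = spec$eps, T_K = spec$temperature)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

## registry of the reference parameter sets -------------------------------

## base conditions: sigma = 0.2125 nm, diameter ratio 1 : 1.25 : 2 : 1.5
## (Mg2+, Na+, Cl-, solvent), eps 78.5, T 298 K, R = 1.5 nm,
## Q = 0.102 C/m^2, 1 M NaCl + 0.5 M MgCl2, C_S = 27.75 M
.fixture_base <- function(sigma = 0.2125, R = 1.5, Q = 0.102,
                          c_nacl = 1, c_mgcl2 = 0.5, C_S = 27.75) {
  spl <- list(
    species("Mg", sigma, 2, c_mgcl2),
    species("Na", 1.25 * sigma, 1, c_nacl),
    species("Cl", 2 * sigma, -1, c_nacl + 2 * c_mgcl2),
    species("solvent", 1.5 * sigma, 0, C_S))
  if (C_S == 0) spl <- spl[1:3]
  system_spec(spl, macroion(R, Q = Q))
}

.fixture_registry <- function() {
  Qs <- c(0.102, 0.204, 0.306, 0.408)
  reg <- list(base = function() .fixture_base())
  for (cs in c(15, 20, 25, 30, 55.55))
    local({ cs0 <- cs
      reg[[paste0("cs", format(cs0))]] <<- function()
        .fixture_base(C_S = cs0) })
  for (q in Qs) local({ q0 <- q
    reg[[paste0("q", format(q0))]] <<- function() .fixture_base(Q = q0)
    reg[[paste0("qneg", format(q0))]] <<- function() .fixture_base(Q = -q0) })
  for (c0s in c(0.01, 0.1, 1, 2)) local({ c0 <- c0s
    reg[[paste0("salt", format(c0))]] <<- function()
      .fixture_base(c_nacl = c0, c_mgcl2 = c0 / 2) })
  for (r in c(0.5, 1, 1.5, 6)) local({ r0 <- r
    reg[[paste0("R", format(r0))]] <<- function() .fixture_base(R = r0) })
  for (q in Qs) local({ q0 <- q
    reg[[paste0("bulkwater_q", format(q0))]] <<- function()
      .fixture_base(Q = q0, c_nacl = 0.1, c_mgcl2 = 0.05, C_S = 55.55) })
  for (s in c(0.1, 0.15, 0.2125)) local({ s0 <- s
    reg[[paste0("sigma", format(s0))]] <<- function()
      .fixture_base(sigma = s0)
    reg[[paste0("sigma", format(s0), "_nosolv")]] <<- function()
      .fixture_base(sigma = s0, C_S = 0) })
  reg
}

#' Registered reference parameter sets
#'
#' Returns the canonical parameter combinations of the model by name:
#' \code{"base"} (the central system) and its standard variants: solvent
#' concentrations
#' \code{"cs15" "cs20" "cs25" "cs30" "cs55.55"}, surface charge densities
#' \code{"q0.102".."q0.408"} (Q = 0.102..0.408 C/m^2) and their negatives
#' \code{"qneg0.102".."qneg0.408"}, electrolyte concentrations
#' \code{"salt0.01".."salt2"} (0.01..2 M NaCl with half as much MgCl2),
#' macroion radii \code{"R0.5".."R6"} (0.5..6 nm), the dilute
#' bulk-water-solvent sets \code{"bulkwater_q0.102".."bulkwater_q0.408"} (0.1 M NaCl + 0.05 M
#' MgCl2, C_S = 55.55 M), the small-ion-size variants \code{"sigma0.1"},
#' \code{"sigma0.15"}, \code{"sigma0.2125"} and their solvent-free
#' counterparts (suffix \code{"_nosolv"}).
#'
#' @param name Fixture name.
#' @return An \code{sdl_system}.
#' @export
model_fixture <- function(name) {
  reg <- .fixture_registry()
  if (!name %in% names(reg))
    stop("unknown fixture '", name, "'; known: ",
         paste(sort(names(reg)), collapse = ", "))
  reg[[name]]()
}

#' Names of all registered fixtures
#' @return Character vector.
#' @export
fixture_names <- function() sort(names(.fixture_registry()))

#' Synthetic radial profiles with closed-form observables
#'
#' Three kinds: \code{"uniform"} (bulk densities everywhere),
#' \code{"shell"} (a thin shell of monovalent counter-charge -Z_M at radius
#' r0 carried by the first ionic species on top of a neutral background), and
#' \code{"exponential_screening"} (ionic clouds with
#' exp(-kappa(r - a))/r decay reproducing the linearized screened potential).
#'
#' @param kind One of the above.
#' @param spec The system.
#' @param grid An \code{sdl_grid}.
#' @param params List; \code{r0} and \code{width} for "shell", \code{a} for
#'   "exponential_screening".
#' @return A list shaped like an \code{sdl_profiles} (grid, rho, psi).
#' @export
synthetic_profile <- function(kind = c("uniform", "shell",
                                       "exponential_screening"),
                              spec, grid, params = list()) {
  kind <- match.arg(kind)
  r <- grid$r; ns <- length(spec$species)
  rho_b <- sp_density(spec); z <- sp_valence(spec)
  ZM <- spec$macroion$valence
  rho <- matrix(rho_b, grid$n, ns, byrow = TRUE)
  if (kind == "shell") {
    r0 <- params$r0 %||% (grid$R + 0.5)
    width <- params$width %||% (4 * grid$h)
    a <- which(z != 0)[1]
    if (is.na(a)) stop("shell profile needs a charged species")
    bump <- exp(-(r - r0)^2 / (2 * (width / 4)^2))
    norm <- 4 * pi * .cumtrapz(r, r^2 * bump)
    bump <- bump * (-ZM / z[a]) / norm[length(norm)]
    rho[, a] <- rho[, a] + bump
  } else if (kind == "exponential_screening") {
    kap <- debye_kappa(spec)
    a0 <- params$a %||% grid$R
    ## linearized Boltzmann clouds in the DH potential
    psi <- dh_potential(ZM, a0, r, spec)
    for (b in seq_len(ns)) rho[, b] <- rho_b[b] * (1 - z[b] * psi)
  }
  prof <- list(grid = grid, rho = rho, psi = NULL, model = "synthetic",
               spec = spec)
  prof$psi <- mep_from_profiles(prof, spec)
  prof
}

`%||%` <- function(a, b) if (is.null(a)) b else a
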