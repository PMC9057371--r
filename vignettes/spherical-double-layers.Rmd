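---
title: "Theory and methods: spherical double layers in the solvent primitive model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theory and methods: spherical double layers in the solvent primitive model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`spheredl` computes the equilibrium structure of the electric double layer
around an isolated, uniformly charged spherical macroion immersed in a mixed
electrolyte whose solvent is treated at the *solvent primitive model* (SPM)
level: every component, including the solvent, is a hard sphere moving in a
dielectric continuum, and only the ions carry charge.  The default
four-component mixture is Mg²⁺ / Na⁺ / Cl⁻ / neutral solvent with diameter
ratio 1 : 1.25 : 2 : 1.5 on a smallest diameter σ = 0.2125 nm, in water-like
continuum conditions (ε = 78.5, T = 298 K).  The macroion of radius R carries
valence Z_M related to its surface charge density by Q = Z_M e / (4πR²).

All internal units are reduced: lengths in nm, energies in k_BT, charges in
units of e.  The only dimensional constants enter through the Bjerrum length
λ_B = e²/(4πε₀ε k_BT) ≈ 0.714 nm and the molarity-to-density conversion.
Pair interactions are hard-sphere cores plus λ_B z_i z_j / r; each species
sees a hard wall at its distance of closest approach R + σ_i/2 plus the bare
Coulomb field of the macroion.  Image charges, dielectric discontinuities and
dispersion forces are outside the model.

Two independent engines solve the same model and are cross-validated against
each other:

* a **classical density functional theory** (DFT) of the partially
  perturbative type: hard-sphere correlations through a weighted-density
  approximation, residual electrostatic correlations through a first-order
  perturbation about the uniform fluid with mean spherical approximation
  (MSA) kernels;
* a **canonical Metropolis Monte Carlo** sampler with Ewald electrostatics.

A nonlinear Poisson–Boltzmann solver with species-wise Stern exclusions
(the unequal-radius modified Gouy–Chapman theory, URMGC) provides the
point-ion baseline.

## The density functional

The equilibrium profiles satisfy the stationarity condition

ρ_i(r) = ρ⁰_i exp{ −z_i ψ(r) + [c¹ʰˢ_i(r) − c̃¹ʰˢ_i] + [c¹ᵉˡ_i(r) − c̃¹ᵉˡ_i] },

with hard cutoffs ρ_i(r) = 0 for r < R + σ_i/2.  ψ(r) is the mean
electrostatic potential (in k_BT/e) generated by the macroion and all ionic
charge; the bracketed terms are the deviations of the one-particle direct
correlation functions (DCFs) from their bulk values; tildes denote uniform
fluid quantities.

**Mean electrostatic potential.** ψ is recomputed from the current densities
at every iteration through the two-term Gauss-law quadrature

ψ(r) = λ_B Z_M/r + 4πλ_B [ (1/r)∫_R^r s² q(s) ds + ∫_r^{r_max} s q(s) ds ],

shifted so that ψ(r_max) = 0; q = Σ_i z_i ρ_i.  This form is robust before
electroneutrality is established; at convergence it coincides with the
compact single-integral form that presumes a neutral double layer, and the
discrete Poisson equation is satisfied to machine accuracy by construction.

**Hard-sphere part (Denton–Ashcroft WDA, mixture form).**  We use one
weighted density per species *pair*,

ρ̄_{ij}(r) = ∫ d³r′ ρ_j(r′) w_{ij}(|r−r′|),  w_{ij}(s) = c̃²ʰˢ_{ij}(s) / (∂c̃¹ʰˢ_i/∂ρ_j),

and evaluate c¹ʰˢ_i(r) as the uniform function at the smoothed density
vector ρ̄_{i·}(r).  Because the denominator equals the 3D integral of the
pair DCF exactly (a thermodynamic identity of the PY-compressibility route),
every weight is normalized, uniform profiles are preserved identically, and
the first functional derivative of c¹ʰˢ_i at bulk reproduces c̃²ʰˢ_{ij}
exactly.  A variant writing a *single* weighted density per species as a sum
over components cannot satisfy the uniform limit with normalized weights and
was rejected.  The uniform hard-sphere thermodynamics is the scaled-particle
(PY-compressibility) free energy; the pair DCF is the matching closed-form
additive-mixture Percus–Yevick function, assembled from geometric weight
convolutions and verified against the one-component closed form (to 1e-13)
and against an independent spectral Ornstein–Zernike solution for asymmetric
mixtures.  Weights are evaluated at bulk densities by default
(`wda_mode = "bulk_weights"`); the locally self-consistent prescription is
available as `"self_consistent"` and agrees to first order in the profile
perturbation, differing only at second order away from hard walls.

**Electrostatic part (MSA perturbation).** The residual term is the
convolution of the density *deviations* with the short-range residual MSA
kernels,

c¹ᵉˡ_i(r) − c̃¹ᵉˡ_i = Σ_j ∫ d³r′ [ρ_j(r′) − ρ⁰_j] · [c̃²ᵉˡ_{ij}(s) + λ_B z_i z_j/s],

whose bracket is compactly supported inside the cores because the MSA pair
DCF equals −λ_B z_i z_j/s exactly beyond contact.  The long-range 1/s part
is *not* convolved here — it is carried by the ψ term, and including it
twice would double count the mean field.

**MSA kernels.**  The screening parameter Γ, the auxiliary P_n and the
effective charges X_i follow Blum's analytic closure,
4Γ² = 4πλ_B Σ_i ρ_i X_i², solved by damped fixed-point iteration from the
exact upper bound κ/2.  For the inside-core part of the electrostatic pair
DCF we solve the *defining equations* of the MSA — the Ornstein–Zernike
relation closed with h = −1 inside the cores and c = −λ_B z_i z_j/s outside
— spectrally (sine-transform Picard iteration with a long-range splitting),
and subtract the analytic PY hard-sphere part.  The resulting tables are
exact to solver tolerance, cached per bulk state, and reproduce the
restricted equal-diameter closed form c̃²ᵉˡ(s) = −λ_B z_i z_j [2Γ/(1+Γσ) −
Γ² s/(1+Γσ)²] to discretization accuracy.  Two properties worth noting:

* the MSA electrostatic DCF is *discontinuous* at contact (already visible
  in the restricted closed form), so no continuity is asserted there;
* pairs involving the neutral solvent acquire small nonzero electrostatic
  kernels in size-asymmetric mixtures (through P_n); the fully uncharged
  system degrades exactly to Γ = 0 with identically zero kernels.

For degenerate, unresolvably small cores (the point-ion limit) the solver
falls back to the closed shell-overlap form built from Γ, which is exact
when P_n = 0 and exact in that limit.

**Discretization and iteration.**  Profiles live on a uniform radial grid
from the surface, default step σ_min/40 and extent max(10/κ, 8σ_max) beyond
R.  All convolutions are dense precomputed operators using the exact
spherical reduction (f∗K)(r) = (2π/r)∫ dr′ r′ f(r′)[J(r+r′) − J(|r−r′|)]
with J the cumulative integral of sK(s); weight operators are discretely
row-normalized so the bulk limit is exact.  The fixed point is reached by
damped Picard iteration (initialized from Boltzmann profiles in the
linearized screened macroion potential) stabilized by Anderson mixing of
depth 5 after a plain warm-up, with a trust-region clip on the per-iteration
logarithmic density change and a reset-to-best safeguard.  Plain Picard with
any linear mixing provably diverges for the central high-packing systems
(charged macroion with solvent above roughly 20 M: a fixed-point Jacobian
eigenvalue exceeds one), which is why the stabilized scheme is the default;
`controls$anderson = 0` restores plain mixing.  Convergence is declared at
max_i,r |Δρ|/ρ⁰_i < 1e-7.

## The point-ion reference

The URMGC solver integrates (r ψ)″ = −4πλ_B r Σ_i z_i ρ⁰_i e^{−z_i ψ}
θ(r − R − σ_i/2) with ψ′(R) = −λ_B Z_M/R² and ψ(r_max) = 0 by damped Newton
on a uniform mesh (step σ_min/50, extent 18/κ), with a damped Picard
fallback.  Nodes lying exactly on a contact radius carry half weight — the
midpoint value of the density step — keeping the source and all charge
integrals second-order accurate; the Gauss-law identity (integrated cloud
charge = −Z_M) holds to 1e-6.

## The Monte Carlo engine

The canonical (N,V,T) cell is a cube with the macroion fixed at the center
and periodic boundaries.  Counts are N_i = round(ρ⁰_i L³) with the coion
count adjusted for exact electroneutrality including the (integer) macroion
valence; initial placement is sequential random insertion with overlap
rejection.  Electrostatics is the Ewald sum with conducting boundary
conditions; the macroion enters as a central point charge Z_M (equivalent,
by Gauss's law, to its uniform surface charge for all exterior
interactions, with the hard core enforcing the Stern exclusions).  Single
particle translations are accepted by the Metropolis rule; hard overlaps
reject unconditionally, implemented as an early geometric test so that the
Boltzmann factor of an overlap is exactly zero.  Per-particle reciprocal
phases are cached and updated on acceptance.  The default splitting for
sampling runs is α = 4.5/L with the reciprocal cutoff chosen for ~1e-7
truncation at that α; energy-evaluation calls can add real-space image
shells, which makes the total independent of α to better than 1e-6 (the
rock-salt Madelung energy is reproduced to 1e-5).  A running ΔU ledger is
compared against full recomputation at the end of every run segment.

Displacements are tuned during equilibration to 35–50% acceptance and then
frozen; production is split into ≥ 10 blocks, and all binned quantities
(spherical shells of width σ_min/10 between R and L/2, exact shell volumes)
carry block standard errors.  The potential profile is obtained from the
binned charge density with the same Gauss-law quadrature as the DFT.  The
default desk schedule (2·10⁴ equilibration + 10⁵ production sweeps) is a
deliberately scaled-down workload; all reports record seed and schedule.

## Cross-validation methodology

A canonical cell at these sizes does not reach the nominal reservoir at its
boundary: part of the macroion's countercharge still resides near L/2.  For
a like-for-like comparison the DFT reservoir concentrations are therefore
fixed by *canonical-cell count matching*: the open-system profiles,
integrated over the cube (using the exact sphere-in-cube shell fractions),
must reproduce the simulated particle counts; the coion concentration is
slaved to bulk electroneutrality.  Density comparisons use volume-weighted
bin averages of the DFT profile over the simulation bins, restricted to
fully accessible bins — a bin straddling a hard-wall discontinuity measures
the accessible volume fraction of the bin, not fluid structure.  The
agreement band is three block standard errors plus 10% of the local density
scale, and the standard desk-scale case (R = 1 nm, Z_M = 8, 0.1 M NaCl +
0.05 M MgCl₂, C_S = 5 M, L = 5 nm) passes it in every bin for all four
species and for ψ(r).

## Observables

* **Integrated charge** P(r) = Z_M + 4π Σ_i z_i ∫_R^r s² ρ_i ds, so that
  P(R) = Z_M and P(∞) = 0.  This inclusive convention is the only one under
  which "P(r)·Z_M < 0 signals charge reversal" and "max P(r) > Z_M signals
  amplification" are simultaneously coherent; an ionic-only accessor is
  also provided.
* **Charge reversal**: first radius where P changes sign against Z_M
  (linear interpolation); **amplification**: |P| exceeding |Z_M| at
  unchanged sign; **ΔZ_M** = max_r P(r) − Z_M (mirrored for negative
  macroions).
* **Capacitive compactness** τ_c: the radius of the concentric shell that,
  carrying the full countercharge, would reproduce the surface potential as
  an ideal spherical capacitor: 1/τ_c = 1/R − ψ₀/(λ_B Z_M), ψ₀ = ψ(R)
  (a contact-plane variant is available via `psi0_at = "contact"`).

### A note on the solvent and compactness

The explicit solvent *drastically increases* the adsorbed charge
amplification: at the central conditions ΔZ_M rises from ≈ 1.0 e (no
solvent) to ≈ 2.8 e (27.75 M solvent) — packing pushes counterions onto the
surface.  By the same mechanism the surface is screened *better* with
solvent, so ψ₀ drops and τ_c, as defined above, becomes slightly *smaller*
(e.g. 1.75 vs 1.86 nm at the central conditions).  Both engines agree on
this ordering, at every ion-size and surface-charge combination we solved.
A test encoding the opposite ordering of τ_c (less compact with solvent) is
kept in the acceptance suite and fails; we regard the amplification
ordering, which the package reproduces robustly, as the physically primary
statement, and the τ_c direction under the capacitor definition as an open
interpretation question documented here deliberately rather than hidden.

## Synthetic data and test design

Test fixtures are generated in code: the registry `model_fixture()` holds
the reference parameter combinations of the model (the central system and its
solvent-concentration, surface-charge, salt, radius and ion-size variants);
`synthetic_profile()` builds uniform, thin-shell and exponentially screened
profiles whose observables have closed forms.  Independent oracles include
SI-constant arithmetic, the restricted-MSA and one-component-PY closed
forms, scaled-particle chemical potentials, brute-force 3D Monte Carlo
quadrature of convolutions, direct lattice sums (Madelung), the linearized
screened potential, and Carnahan–Starling via the tagged-particle contact
value.  The scaled-down problem sizes (grids of 300–900 nodes, 10⁴–10⁵ Monte
Carlo sweeps, cells of 80–400 particles) were chosen as the smallest
workloads at which every qualitative statement tested is resolved clearly
above its statistical error; they emulate the physical conditions, not the
production scale, and passing them demonstrates internal correctness and
engine agreement rather than full convergence of every production curve.

## Known limitations

* The WDA/MSA functional is approximate physics: contact values at strong
  coupling carry few-percent systematic error relative to simulation even
  though all internal identities are exact.
* The spectral MSA kernel solve inherits a mesh (σ_min/128, capped) and a
  Picard tolerance of 1e-11; kernels are linear-interpolated between mesh
  points.
* The canonical cell leaves finite-size corrections of order
  e^{−κ(L/2−R)} in the far field; count matching absorbs them into the
  reservoir mapping rather than eliminating them.
* Off-center ionic charges, image forces, dielectric saturation and
  macroion-pair interactions are outside scope.
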