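---
title: "Activity-based segregation of interphase chromosomes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-based segregation of interphase chromosomes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actseg)
```

## The model

Interphase chromosomes are coarse grained as linear bead-spring polymers:
one soft sphere per 1 Mb of chromatin, 22 autosomal pairs plus two X
chromosomes (the female diploid karyotype), 6098 monomers in total,
confined to a spherical or ellipsoidal nucleus. The package simulates the
overdamped (inertia-free) Langevin dynamics of this system with the
explicit Euler update

    r_i <- r_i + (dt / zeta) * F_i + sqrt(2 * kB * T_i * dt / zeta) * eta_i

where `eta_i` are independent standard normal 3-vectors and `T_i` is a
**per-monomer effective temperature**. This is the model's central idea:
ATP-consuming chromatin remodeling and transcription exert stochastic
forces on gene-rich chromatin far exceeding thermal ones, and over coarse
time scales those forces act like an elevated temperature in the noise
term only. Monomers are classified by their local gene density (genes/Mb
in the 1 Mb bin): the most gene-dense fraction (`active_fraction`, default
the top 5% genome-wide) is "active" and simulated at `T_a` (default 20, in
units of the physiological temperature, the scale of the free energy
liberated by ATP hydrolysis), all others stay at `T_eq = 1`. Because the
drag `zeta` is uniform, the Einstein relation holds per monomer but is
violated across monomers: the steady state is genuinely non-equilibrium,
and hot (gene-dense) monomers spontaneously segregate toward the nuclear
interior — activity-based segregation. No explicit ordering force exists
anywhere in the force field.

Deterministic forces `F_i` comprise:

* **backbone springs** between consecutive monomers of a chain,
  `E = k_bond/2 (d - r0)^2`;
* **random loop springs**: each monomer is independently an anchor with
  probability `p_loop` and is paired with a uniformly chosen partner on
  its own chain; loops are permanent and `loop_k_multiplier = 10` times
  stiffer than backbone springs. Three presets (`low`, `mid`, `high`) are
  calibrated so the expected counts on the 6098-monomer system are 424,
  712 and 1404 loops;
* **Gaussian-core repulsion** between all monomer pairs,
  `V0 exp(-d^2 / (2 sigma^2))`, the standard soft potential for
  interpenetrating polymer coils — chains can cross, as the model has no
  topological constraints;
* **confinement**: zero inside the nucleus, harmonic in the outside
  distance to the surface (`k_wall/2 d_out^2`). Ellipsoids of revolution
  (oblate or prolate, volume-matched to the reference sphere) use the true
  Euclidean surface distance, so all points at a common distance from the
  envelope feel a common potential;
* optionally, a **selective nuclear-envelope (NE) attraction** felt by
  active monomers only: a Gaussian well of depth `eps_ne` and range
  `lambda_ne` with its minimum on the envelope. This competes with bulk
  segregation and, when it wins, stabilizes the "inverted" nuclear
  architecture (gene-rich chromatin at the periphery) seen in specialised
  cell types.

## Units

Reduced units throughout: the monomer diameter `sigma` is the length unit
(a 0.5 µm chromatin domain), `kB T_eq` the energy unit, and the drag
coefficient `zeta` the friction unit, which fixes the time unit `tau`.
The nuclear radius is `R0 = 10 sigma` (a 10 µm nucleus) and the time step
`dt = 0.01 tau`.

## Parameters and defaults

| parameter | default | units | meaning |
|---|---|---|---|
| `k_bond` | 5 | energy/length² | backbone spring; entropic-spring scale (~3–5 kT/σ²) of a 1 Mb domain |
| `r0` | 1 | σ | bond rest length (equilibrium domain separation) |
| `V0` | 2 | kT_eq | pair energy at contact, of order thermal |
| `sigma` | 1 | σ | Gaussian-core width = monomer diameter |
| `k_wall` | 50 | energy/length² | confinement stiffness |
| `loop_k_multiplier` | 10 | — | loop springs vs backbone springs |
| `eps_ne` | 50 | kT_eq | NE well depth (2.5 × T_a) |
| `lambda_ne` | 1 | σ | NE well range |
| `r_cut` | 3 | σ | pair cutoff (tail < 1.2% of V0) |
| `active_fraction` | 0.05 | — | top-gene-density fraction flagged active |
| `T_a` | 20 | T_eq | active effective temperature |
| `dt` | 0.01 | τ | Euler time step |

**Why these spring constants.** The explicit Euler update of an overdamped
spring of constant `k` is stable only if `dt * 2k / zeta < 2`. With
`dt = 0.01` this caps the stiffest spring — the loop springs, fixed at ten
times the backbone — at 100, hence `k_bond = 5` (loop springs 50,
stability factor 1.0) and `k_wall = 50` (factor 0.5, and the wall acts on
single coordinates). These values also have the right physics: the
entropic spring constant of a ~1 Mb domain is a few kT per σ², and the
wall confines equilibrium monomers to within ~0.14 σ rms penetration
(hot monomers at `T_a = 20` penetrate ~0.6 σ rms — the envelope is soft,
as a lipid/lamin shell is).

**Why `eps_ne = 50`.** A well must compete with the active noise scale to
retain a hot monomer: depths of order `T_a` or below are escaped
instantly and leave the conventional arrangement untouched. A depth of
2.5 × `T_a` with a one-diameter range produces a stable, reproducible
inversion while remaining short-ranged. Both values are ordinary config
keys (`forcefield.eps_ne`, `forcefield.lambda_ne`) and deserve scrutiny in
any quantitative application.

**Instability guard.** At `T_a = 20` the *noise* displacement of a hot
monomer averages ~1 σ per step — large single-step moves are part of the
model, not an error. The integrator therefore guards the *deterministic*
drift `dt |F_i| / zeta`, aborting above `guard_sigma = 5` σ/step:
a genuine stiffness blowup grows exponentially and trips this within a few
steps, while healthy runs stay below ~2 σ (reached only in the initial
push-off transient of a freshly laid compact random walk). The run report
exposes the observed maximum.

## Synthetic gene-density tracks

Per-Mb gene counts from genome databases are not redistributable, so the
package synthesizes them: log-normal draws per 1 Mb bin (heavy-tailed, as
empirical per-Mb gene counts are), linearly rescaled per chromosome so
that constrained chromosomes hit their mean gene density **exactly**. The
packaged default track pins the four chromosomes the model is usually
probed with — chr19 (62.03 genes/Mb, 60 Mb), chr18 (18.64, 78 Mb), chr12
(30.92, 134 Mb), chr20 (29.71, 63 Mb) — and gives every other chromosome a
default mean of 27 genes/Mb with `sdlog = 1` heterogeneity. Remaining
chromosome lengths follow a standard human assembly rounded to Mb, with
chromosome 1 absorbing the rounding remainder so the haploid total is
3049 Mb (diploid 6098 monomers).

What the synthetic track reproduces: the ranking and spacing of
chromosome-mean gene densities, fractional densities, and strong bin-to-bin
heterogeneity, which is what the top-5% rule consumes. What it does not:
the true positional autocorrelation of gene density along each chromosome
(isochores, gene deserts) and any cell-type-specific expression pattern.
Tests passing on this input therefore validate the *mechanism* —
segregation by activity class — not the detailed shape of any real
chromosome's radial profile.

The "top 5%" cutoff is applied globally across all 6098 monomers (not per
chromosome), with `n_active = round(0.05 N)` (half away from zero) and
deterministic tie-breaking by gene content, then monomer id.

## Numerical choices

* **Pair interactions** use a counting-sorted cell list (cells of
  `r_cut/2`, widened automatically for dilute systems), iterating occupied
  cells with a half stencil so every pair is visited once;
  action–reaction is exact by construction. `total_forces()` evaluates the
  Gaussian exactly; the integrator uses an 8192-point linear interpolation
  of the force factor versus squared distance (error ~3e-7 · V0, far below
  discretization noise) for speed. Inside the cutoff the pair energy is
  shifted so it reaches zero continuously at `r_cut`.
* **Spheroid surface distance** solves the ellipse nearest-point equation
  by bisection to ~1e-13, with the degenerate on-axis branches (where the
  nearest point leaves the symmetry axis) handled explicitly. Only
  ellipsoids of revolution are supported — the geometry the model's
  oblate/prolate nuclei need. Two independent implementations exist (R,
  used by the analysis layer, and C++, used by the integrator) and are
  cross-checked against a brute-force surface search in the tests.
* **Effective radial coordinate**: in ellipsoids, radial statistics are
  binned by `r_eff = R0 (1 - d_in / min(a, c))`, which maps
  equidistant-from-envelope points to one coordinate; in spheres this is
  `|r|` exactly.
* **S(R) normalization** is integral-to-1 over the radial coordinate
  (the reference curves are in arbitrary units); for a uniform spatial
  distribution S(R) then rises as R². Standard errors come from block
  averaging (10 blocks) over frames.
* **Territory index** `N_c(R_sphere)`: per monomer, +1 for every other
  monomer of the same chain and −1 for every foreign monomer strictly
  within `R_sphere`, averaged over monomers; grid-accelerated with the
  exhaustive double loop kept as the reference. "Same chain" means the
  same homolog copy by default (FISH paints territories per homolog); a
  switch pools copies. The self-monomer is excluded so the small-radius
  limit is 0.
* **Randomness**: one top-level seed fans out to named sub-streams
  (genome synthesis, loop drawing, initial placement, dynamics noise);
  noise is drawn in monomer order from R's RNG, so identical (config,
  seed) reproduce byte-identical trajectories.
* **Initialization** lays each chain as a compact random walk with exact
  bond length, uniform chain starts, rejection-sampled to stay inside the
  confinement. Steady-state observables were verified to be independent
  of the initial configuration.

## What the tests simulate

The full-scale experiment (6098 monomers for ≥1e7 steps) is a
cluster-scale computation. The package's own checks run a scaled system
chosen to preserve the physics: 8 chains × 100 monomers in a sphere of
`R0 = 10 (800/6098)^(1/3) ≈ 5.08 σ` (equal volume fraction), 10% active at
`T_a = 20`, 2×10^5 steps for the segregation runs (five independent
seeds), 6×10^4 further steps for the NE switch-on continuations, and
~10^5 steps for the territory and equilibrium runs. At these sizes the segregation gap (mean
radius of inactive minus active monomers, relative) reaches 10–15%, the
NE attraction inverts its sign, and the high-preset loop system shows a
positive territory-index peak while the loop-free system stays negative —
the qualitative steady-state signatures of the model.

## Known limitations

* No hydrodynamic interactions, no chain-uncrossability, no bending
  stiffness, no hard cores: soft Gaussian repulsion is the only excluded
  volume, as in the underlying coarse-grained model.
* The effective-temperature description compresses all ATP-driven
  activity into the noise amplitude; oscillatory or directed active
  forces are out of scope.
* Gene density is a fixed proxy for activity: cell-type-specific
  transcription is deliberately not modeled.
* The NE interaction parameters are declared defaults, calibrated to
  produce a stable inversion, not fitted to data.
* Real-time conversion of `tau` to seconds depends on the assumed
  nucleoplasm viscosity and is not reported by the package.
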