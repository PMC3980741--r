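---
title: "Macroquantum dynamics: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Macroquantum dynamics: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macroquant)
```

## The model

`macroquant` implements a family of self-organization models built around a
generalized Schrödinger equation in which Planck's constant is replaced by a
system-specific action constant.  The physical picture is a medium whose
elementary trajectories are fractal with dimension 2 (Markovian loss of
information between steps): elementary displacements carry a stochastic part
`d\xi = \zeta \sqrt{2 D} |dt|^{1/2}` whose amplitude is set by a constant `D`
(units length²/time).  Averaging over the infinite family of such paths, and
accounting for the forward/backward two-valuedness of velocities that
non-differentiability induces, the equation of motion integrates to

    i S0 ∂ψ/∂t = -(S0²/2m) Δψ + φψ,      S0 = 2 m D,

the ordinary Schrödinger equation with `ħ → S0`.  Everything quantum-like in
the package—quantized stationary states, node/peak structure, the quantum
potential—derives from this one constant.  Setting `D = ħ/(2m)` recovers
textbook quantum mechanics exactly, which is the package's main correctness
oracle (`stationary_states()` against the closed-form oscillator and box
spectra, and an SI-units electron oscillator).

Four equivalent representations of the same dynamics are implemented and
cross-checked:

* **wave**: the complex `ψ` on a grid (`wave_field`);
* **hydrodynamic**: `P = |ψ|²` and `V = 2D∇θ`, obeying continuity plus an
  Euler equation with the quantum potential
  `Q = -2 m D² Δ√P/√P` (`wave_to_hydro`, `quantum_potential`,
  `evolve_hydro`);
* **two-fluid**: the real pair `(V, U = D∇ln P)` with two coupled Euler-type
  equations (`two_fluid` returns their finite-difference residuals);
* **diffusive**: `(P, v₊)` with a Fokker–Planck equation and the
  velocity-dependent potential `Q₊ = -mD(v₊·∇ln P + DΔln P)`
  (`wave_to_diffusive`, `quantum_potential_plus`, `evolve_fokker_planck`).

The sign reversal of `Q` maps the self-organizing dynamics onto ordinary
diffusion (`diffusion_potential`, `evolve_hydro(quantum = "reversed")`): the
same `ΔP/P` shape, opposite sign, entropy increasing instead of structure
forming.

A second, independent layer works in the *space of scales*: lengths measured
at resolution `ε` obey first- or second-order differential equations in
`ln ε`, giving broken power laws (`fractal_length`), log-periodic
corrections (`log_periodic_length`, `fit_log_periodic`), linearly drifting
fractal dimensions (`scale_dynamics_length`), an impassable wall with
diverging local dimension (`scale_oscillator_length`,
`wall_dimension_profile`—the cell-wall model), and a Lorentz-like law with
an invariant limiting scale (`special_relativity_djinn`).  A particle-in-a-box
spectrum in `ln ε` (`hierarchy_modes`) quantizes nested levels of
organization; its fundamental peaks at the geometric mean of the extreme
scales (`mid_scale`), which is where the printed worked examples
(2.3×10³⁰ Planck lengths; 40 µm between 0.5 Å and 30 m) come from.

## Parameters that matter

* `D` (> 0, length²/time) and `m` (> 0): never defaulted by the engine; a
  run declares its own consistent unit system.  `S0 = 2mD` is derived, not
  settable.
* `omega` (harmonic traps): sets the oscillator quantum `S0·ω` and the
  ground-state width `σ_P = sqrt(D/ω)`; grids should resolve `σ_P` with
  ~20+ points and extend ~10 σ per side.
* `beta` (≥ 0): cubic Ginzburg–Landau coefficient, `2mβ|ψ|²ψ` in the
  evolution; `β = c_s²/2ρ₀` in the acoustic derivation.  Handled by Strang
  splitting around the unitary linear step, so the norm is conserved for any
  `β`.
* `threshold`/`floor_frac` arguments: all logarithmic or ratio quantities
  (`∇ln P`, `Δ√P/√P`) are masked (NA) where `P` falls below a floor
  (default 10⁻¹² of the peak), because the continuum formulas are singular
  on zero-density sets; masked cells are excluded from residual norms.
  Node counting uses an amplitude floor of 10⁻⁶ of the peak and peak
  counting a topographic-prominence threshold of 0.1 of the maximum.

## Numerical choices

**Discretization.** Second-order central Laplacian on uniform grids;
`"box"` means Dirichlet walls (`ψ = 0`), `"periodic"` wraps.  The
discretized Hamiltonian is symmetric by construction (asserted), and
eigenvalue errors fall by ~4× per grid doubling (tested).  Eigensolves use
the dense symmetric solver, which bounds practical problems to ≲ 4096 grid
points—ample for the 1D/2D demonstrations this package targets.

**Time stepping.** The wave evolution uses the Cayley (Crank–Nicolson)
propagator, exactly unitary for the linear problem; nonlinearity enters by
operator splitting.  A warning fires when `dt` exceeds `h²/(2D)`, above
which phases degrade.

**The hydrodynamic integrator.** `evolve_hydro` uses the Lagrangian
quantum-trajectory method: grid nodes become fluid particles carrying the
initial density, and the density follows from the deformation Jacobian,
`P = P₀/J`.  The decisive property is that the log-amplitude in the
co-moving frame, `ln a = ln a₀ - ln(J)/2`, keeps full *relative* precision
at any tail depth, so the quantum force needs no density floors.  This
choice was made after systematic experiments with Eulerian
finite-difference forms (in `(P,V)`, `(ln P, V)` and `(√P, V)` variables,
with artificial viscosity and tail cut-offs): all of them excite the known
low-density instability of discretized Madelung systems, in which relative
perturbations amplify like the inverse amplitude while travelling down a
density slope.  That amplification is bounded by the square root of the
density contrast across the domain, which leads to a genuine validity
limit stated in the docs: two-route (wave vs hydro) agreement at the 10⁻³
level is achievable for nodeless flows of bounded contrast—e.g. modulated
periodic backgrounds—while a Gaussian packet on a wide domain (contrast
beyond 10¹²) defeats any fixed-grid scheme of this class over long
horizons.  The package therefore demonstrates Madelung equivalence on a
strictly positive periodic flow over half a revival time (measured L²
distance ~5×10⁻⁵), and uses the harmonic trap for the checks that are
well-posed there: stationary-state staticity and spectral reduction.
Trajectory crossings (`J → 0`) raise a caustic diagnostic: nodes and
shocks are exactly where the potential-flow description fails.

**The reversed branch.** Integrating the sign-reversed Euler system as an
initial-value problem is ill-posed off the diffusion manifold—spurious
modes grow like a backward heat equation at grid scale.  This mirrors the
structural asymmetry of the theory itself, in which the backward
Fokker–Planck equation is a derived relation, not a founding equation of
any classical process.  Accordingly the sign-reversal claims are verified
by (i) the Euler residual of the reversed equation evaluated on the mapped
free-diffusion Gaussian across a decade of spreading, (ii) short-horizon
reversed evolution tracking the closed-form heat solution, and (iii)
strict entropy increase along the (well-posed, forward) Fokker–Planck
flow.  The backward Fokker–Planck equation is only integrated in paired
mode, with `v₋` slaved to `v₊ - 2D∇ln P`; staggered half-point fluxes keep
its anti-diffusive term cancelled at every wavenumber.

**Phase reconstruction.** `hydro_to_wave` integrates `V/(2D)` along a
spanning tree (first axis, then the rest) with the trapezoid rule, and
accepts only potential flows: the maximal elementary-loop circulation
decides the precondition (typed error `mq_nonpotential`).  The default
tolerance (10⁻⁶ rad) expects discretely consistent velocity fields;
velocities sampled from analytic potentials are curl-free only to O(h²)
and should be checked against a matching tolerance.

**Entropy.** For free Gaussian diffusion the Gibbs entropy grows like
`ln(σ₀² + 2Dt)/2`—monotonically but logarithmically, not linearly in time.
The package asserts strict monotonicity only.

**Log-periodic fitting.** `fit_log_periodic` runs a grid search over the
log-frequency `ω` with `(ln a, ν, b·cos, b·sin)` profiled linearly on
`ln(value)` (log-periodic fits are notoriously multimodal in `ω`), then
polishes with Levenberg–Marquardt using an analytic Jacobian, which takes
noiseless synthetic series to machine-level residuals.  A free phase is
included: the pure `cos(ω ln ε)` form fixes the phase only up to the
choice of the unit of `ε`.  Significance is scored by permutation of the
detrended residuals (default 200 shuffles, seeded): the statistic is the
RSS reduction of the oscillatory component maximized over the `ω` grid,
so the look-elsewhere effect of the grid search is built into the null.

## What the synthetic generators emulate

`generate_fixture` produces Gaussian densities, smooth seeded random
potentials, log-periodic series with multiplicative noise, solid-body
vortex flows (deliberately non-potential) and dopant density dips.  The
log-periodic generator draws `value = a ε^ν (1 + b cos(ω ln ε))` on a
log-spaced grid with 1% multiplicative Gaussian noise by default
(n = 50 samples over three decades)—an idealization of event-series data
in which the oscillation is exactly in the model class, the noise is
uncorrelated and the sampling is regular in `ln ε`.  Passing the recovery
tests under these conditions shows the estimator works where the model
holds; it says nothing about series with correlated noise, irregular
sampling, or oscillations that are not of the fitted form.  Likewise, the
turbulence simulator produces ideal K41 velocity paths (exact
`|dt|^{1/2}` increments, optional linear friction): it echoes the
structure-function scaling and the same-order acceleration/increment
dispersions seen in Lagrangian data, not the intermittency corrections of
real flows.

## Known limitations

* Hydrodynamic evolution is 1D and requires nodeless, bounded-contrast
  densities (see above); wave evolution and the representation maps
  operate in 1–3 dimensions.
* Dense eigensolves limit grids to ≲ 4096 points; 2D duplication demos use
  anisotropic traps (isotropic first excited levels are degenerate and are
  rejected as non-generic).
* The morphogenesis layer is deliberately qualitative: petal curves follow
  the stated constant-tension construction (constant-magnitude transverse
  acceleration in the plane containing the growth axis, free magnitude
  parameter `tension`, `k` equispaced azimuths with zero phase offset);
  the gravity/tension balance of an opening flower and any further
  quantum numbers of hierarchical complexity are not modelled.
* The velocity-space turbulence layer implements the correction terms
  (potentials, forces, variance bookkeeping), not a Navier–Stokes solver.
* Problem sizes in tests and the acceptance script (grids of 64–1024
  points in 1D, ≤ 48³ in 3D, 10⁵ stochastic samples, 20-seed recovery
  loops) were chosen as the smallest at which each scheme is converged at
  its stated tolerance.

## A worked example

```{r example}
p <- macro_params(D = 0.5, m = 1)          # S0 = 1
g <- grid_spec(400, extent = 14, origin = -7)
sol <- stationary_states(potential_spec("harmonic", omega = 1, center = 0),
                         g, p, n_states = 3)
sol$energies          # ~ S0 * omega * (n + 1/2) = 0.5, 1.5, 2.5
vapply(sol$states, count_nodes, integer(1))
Q <- quantum_potential(sol$states[[1]])
phi <- potential_field(potential_spec("harmonic", omega = 1, center = 0), g, p)
core <- density_of(sol$states[[1]]) > 1e-3 * max(density_of(sol$states[[1]]))
range((Q + phi)[core])    # constant = E0 on the support: stationarity
```
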