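---
title: "Methods: a desk-scale lattice Boltzmann model of basilar-artery stroke in the circle of Willis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale lattice Boltzmann model of basilar-artery stroke in the circle of Willis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical problem

The circle of Willis is the ring of arteries at the base of the brain that
joins the posterior supply (the basilar artery, BA) to the anterior supply
(the two internal carotid arteries, ICAs) and feeds the six cerebral outlet
arteries: the left/right posterior (PCA), middle (MCA) and anterior (ACA)
cerebral arteries. Its communicating segments — the posterior communicating
arteries (PCoAs) joining each carotid to the ipsilateral PCA, and the
anterior communicating artery (ACoA) joining the two ACAs — allow flow to
be rerouted when a feeder is blocked. A complete ring is the exception
rather than the rule; missing PCoAs are common, which is why this package
treats the ring's topology as a modelling variable.

`willisflow` simulates the seconds during and immediately after an ischemic
stroke of the basilar artery: the BA inlet waveform is attenuated by one of
five envelopes while the carotid inlets stay healthy, and the observable of
interest is how much flow each of the six outlets retains relative to a
healthy run of the same configuration. Blood reaching the outlets is used
as a proxy for perfusion of the downstream territory; the network beyond
the ring is not modelled.

## Solver

The flow solver is a single-relaxation-time (BGK) lattice Boltzmann method
on the D3Q19 stencil. Per fluid voxel, 19 populations `f_i` relax towards
the second-order Maxwell–Boltzmann equilibrium and stream to their lattice
neighbours each step; density and momentum are the zeroth and first
moments, pressure is `c_s^2 rho`, and the kinematic viscosity is
`nu = c_s^2 (tau - 1/2) dx^2 / dt` with `c_s^2 = 1/3`. The update order is
fixed — collide, stream, walls, velocity inlets, pressure outlets — and
observables are sampled after boundary resolution. Two implementations of
one update exist: a vectorised R reference (`collide_bgk()`,
`stream_populations()`, `apply_walls()`, `apply_velocity_inlet()`,
`apply_pressure_outlet()`, composed by `lbm_step()`) and the fused C++
driver used by `run_simulation()`; the test-suite holds them to 1e-12
agreement on a driven tube, so the fast path is always checkable against
the legible one.

Assumptions: blood is Newtonian with `nu = 4.0e-6 m^2/s` and density
1000 kg/m^3 (the standard whole-blood values; on the reference 25 µm / 1 µs
discretisation these give `tau = 0.5192`); vessel walls are rigid; the flow
stays in the low-Mach regime (`Ma = u_lat * sqrt(3)` capped at 0.1 by
default — beyond that the scheme's compressibility error grows as `Ma^2`).
D3Q19 is chosen as the standard compromise between isotropy and memory
among the nearest-neighbour stencils; collision is strictly BGK (no
multi-relaxation variants).

Divergence handling: any non-finite population or non-positive density
aborts the run with the offending site and step, because silent NaN
propagation is the dominant failure mode of lattice Boltzmann codes.
Everything is double precision and there is no stochastic element, so runs
are bit-reproducible on one platform.

## Boundary conditions

*Walls* are resolved by halfway bounce-back: the no-slip plane sits half a
link outside the last fluid voxel, first-order accurate on staircase
(voxelised) surfaces. We accept staircase walls and compensate with
resolution (validation geometries use at least 20 sites per diameter)
rather than implementing curved-wall interpolation.

*Velocity inlets* prescribe a transient plane profile. Each cap site gets a
weight `w = 1 - (1 - d/d_max)^2` from its in-plane distance `d` to the
nearest wall: zero at the wall, one at the furthest site, and — because
`d = R - r` on a circular cap — exactly the Poiseuille parabola
`1 - (r/R)^2` there. The exact parabolic construction is a design choice;
any formula with those endpoint properties would serve, and the chosen one
is the simplest that reconstructs Poiseuille flow. The link-level closure
is moving-wall (momentum-corrected) bounce-back against a fictitious wall
half a link outside the cap travelling at the target velocity
`u_b = v(t) w(s) n`. It degrades gracefully to a static wall at `v = 0`,
is robust on staircase caps, and realises the imposed per-site velocity to
about 1% on the validation tube.

*Pressure outlets* replace each outlet-plane site by the equilibrium at a
fixed reference density (shared by all outlets; there is no basis for
per-outlet pressures in an idealised geometry) and the velocity of its
interior neighbour. This pins the plane pressure, imposes a zero normal
pressure gradient at zeroth order, and makes a uniform resting state an
exact fixed point. Windkessel-type outlets are deliberately out of scope:
the fixed-pressure construction is the simpler, proven choice for this
solver family, and the quantities of interest here are flow *ratios*
between paired runs, which are insensitive to the common outlet pressure.

A practical compressibility caveat discovered during validation: with a
fixed outlet density, the inlet-side density rises by the viscous pressure
drop `(delta p)/c_s^2`. Steady *volume* fluxes at inlet and outlets then
disagree by exactly that density ratio even though mass flux balances.
Configurations are therefore chosen to keep the lattice pressure drop small
(the bifurcation validation runs at `tau = 0.55`, where the lattice
viscosity — and with it the lattice pressure drop — is smallest, and
balances volume flux to well under 1%).

## Waveforms and stroke scenarios

The healthy inlet signal is periodic with one systolic peak per beat: a
raised-cosine pulse (default width 0.35 of a period, peak at phase 0.2)
over a diastolic floor of 0.25 `v_max`. The default period is 2.6/3 s so
that three beats span 2.6 s, which is the measured flow window after a
0.4 s warm-up during which the amplitude ramps linearly from zero. The
pulse shape stands in for measured velocity traces; a sampled trace can be
imported from two-column text (`import_waveform()`) if one is available.

The five infarct scenarios multiply the BA signal by a continuous,
non-increasing, piecewise-linear envelope sharing one onset (default: the
start of the second beat after warm-up):

1. sudden halt — linear to zero over a quarter heartbeat;
2. slow stoppage — linear to zero at the simulation end;
3–5. linear over a quarter heartbeat to 50%, 30%, 10% of healthy flow,
then constant.

The quarter-heartbeat ramp for scenarios 3–5 matches scenario 1's; onsets,
ramps and peak velocities are all configuration with these documented
defaults. By construction the infarcted signal never exceeds the healthy
signal at the same instant; transiently higher *outlet* flow (as scenario
2 produces mid-beat) is an emergent property of the paired comparison, not
of the inlet.

## Synthetic geometry

`build_idealized_cow()` generates a planar, parametric circle of Willis
from capsule segments (cylinders with hemispherical joins and flat ends
under caps): BA and two ICA inlets, six outlets, and the P1, A1, PCoA and
ACoA connecting segments. Default radii are literature-typical calibres —
ICA 2.0, BA 1.6, MCA 1.4, PCA/ACA 1.2, PCoA/ACoA 0.7 mm — on a ring
spanning roughly 25 × 20 mm, mirror-symmetric about the midline. The
variants remove the left or right PCoA; because the junction balls of the
remaining segments already close the wall smoothly, a removed vessel is
equivalent to one blocked by stagnant fluid. Caps are axis-aligned planes
(a deliberate restriction that keeps inlet weighting and plane flow rates
exact); terminal segments are laid out to respect it.

What the generator emulates: the topology of the ring, realistic calibres,
removable communicating arteries, smooth junctions, and caps suitable for
the boundary constructions. What it does not: patient-specific curvature,
tapering, tortuosity and calibre asymmetry, non-planar (three-dimensional)
ring geometry, and imaging-derived surface roughness. Tests passing on
these geometries therefore validate the solver and the redistribution
*mechanism*; they do not certify patient-specific flow fractions, which
depend strongly on individual anatomy.

Voxelisation classifies a site fluid if its centre falls inside the capsule
union (first-order volume convergence in `dx`), refuses any vessel
resolved under 3 sites per radius, stamps single-plane caps, pads the
domain with solid, and verifies 19-connectivity of the wet region (a
disconnected network is an error listing component sizes). Site centres sit
at `(i - 1/2) dx` on a right-handed grid; grid origins are snapped to
multiples of `dx` so that a mirror-symmetric specification voxelises to an
exactly mirror-symmetric lattice — this is why the bifurcation validation
can demand a 50.0% flow split to numerical precision.

## Observables

Plane flow rates are `Q = dx^2 sum u_n` over a cap (inward-positive at
inlets, outward-positive at outlets). Stroke-to-healthy ratio series divide
window-averaged series (default window: one twentieth of a period — the
figures of interest are beat-scale, so sub-beat smoothing suppresses
sampling jitter without moving cycle averages); samples where the healthy
flow is within 2% of zero are masked, not divided. Summary ratios are
ratios of final-beat cycle averages, which are robust to transients and
exactly recover a scenario's residual fraction in the quasi-steady limit.

Wall shear stress is estimated on wall-adjacent fluid voxels (at least one
face neighbour solid — the face rule keeps the element shell one voxel
thin) from the non-equilibrium stress tensor
`sigma = -(1 - 1/(2 tau)) sum_i c_i c_i (f_i - f_i^eq)`, using each site's
own current moments for `f^eq`. The outward normal is the normalised
central-difference gradient of a 3×3×3 box-smoothed solid indicator, which
is robust on staircase walls; elements with a degenerate normal (isolated
voxels) are skipped and counted. Because the element centre sits about half
a link inside the wall plane, the tensor is linearly extrapolated that
half-link along the normal (using the interior neighbour on the dominant
normal axis) before the traction is projected; on planar Couette flow this
estimator is exact to rounding, and on the voxelised Poiseuille tube at 32
sites per diameter it recovers the analytic wall stress to within 5%,
staircase scatter included. Display exports clamp to 0–20 Pa by default.

## Numerical choices and problem sizes

* **Relaxation time.** Production circle-of-Willis runs use `tau = 0.8`
  (mid-range: comfortably stable, moderate lattice viscosity). The
  Poiseuille validation uses `tau = 1.0`, where the combined BGK plus
  bounce-back truncation error is smallest; the bifurcation balance check
  uses `tau = 0.55` to minimise the compressibility imbalance discussed
  above; the shear-wave viscosity check spans 0.55–1.2.
* **Desk-scale regime.** The reference discretisation (25 µm, 1 µs,
  ~1.7e8 sites) is far beyond desk scale. The default circle-of-Willis
  configuration uses `dx = 0.2 mm` (~6e4 wet sites) and `dt = 1 ms` (from
  `tau = 0.8` at blood viscosity), which caps admissible speeds at about
  0.01 m/s: at this resolution a sub-0.1 Mach number and a tau safely above
  1/2 cannot both hold at physiological peak velocities of 0.4–0.5 m/s —
  resolving that conflict is precisely why high-resolution studies exist.
  Desk runs therefore scale the peak inlet velocities down (BA 0.0072,
  ICA 0.009 m/s, preserving the physiological 0.4:0.5 ratio), dropping the
  Reynolds number from a few hundred to order ten. In this viscous regime
  the outlet split is governed by the network's resistances, so
  *directional* redistribution results (which outlets lose most, how a
  missing PCoA shifts the deficit) are meaningful, while printed
  percentages are regime-specific and not patient predictions. When `dx`
  changes, `dt` rescales diffusively (`dt` proportional to `dx^2` at fixed
  viscosity and tau).
* **Time horizon.** Warm-up 0.4 s plus three beats of 2.6/3 s each: 3.0 s,
  i.e. 3000 steps at desk scale (and exactly 3,000,000 at the reference
  1 µs step). Stroke onset defaults to the start of the second beat; the
  final beat is the summary window.
* **Steady validation runs** stop when the maximum velocity change per
  check interval falls below 1e-6 of the maximum speed (the residual
  transient is then orders of magnitude below the few-percent tolerances
  being tested), with a wall-clock-free step cap as backstop. Validation
  sizes: Poiseuille tube 32 sites/diameter (~6.5e4 sites, a few thousand
  steps), bifurcation ~2.4e4 sites, shear wave 64×4×4, Couette 4×4×16.
  The grid-refinement check compares 12 against 24 sites per diameter.
* **Initialisation.** Runs start from uniform equilibrium at the outlet
  density; inlets ramp up through the warm-up. Validation fits ignore the
  ramp by measuring late windows.
* **Degenerate inputs** are refused with classed errors: non-positive
  viscosities or `tau <= 1/2`, under-resolved radii, disconnected fluid
  regions, empty or non-planar inlets, inlet speeds at the lattice sound
  speed, series that do not span a requested cycle, mismatched grids in a
  comparison.

## Limitations

Rigid walls (no vessel compliance or autoregulatory calibre change, which
act on longer timescales than the simulated seconds); Newtonian rheology;
staircase wall geometry with first-order wall placement; idealised planar
anatomy; no downstream vascular network (outlet flow is a perfusion proxy);
a single shared outlet pressure; and the reduced-Reynolds desk regime for
the full-ring runs. The experiment matrix (`run_matrix()`) and all
geometric and waveform parameters are configuration, so the same pipeline
expresses the reference-scale setup where the computing budget allows it.
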