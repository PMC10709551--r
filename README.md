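# willisflow

A desk-scale, three-dimensional lattice Boltzmann simulator for blood flow
in the circle of Willis — the arterial ring at the base of the brain that
can reroute flow when one of its feeding vessels is blocked. The package is
aimed at computational-hemodynamics work: it simulates an ischemic stroke of
the basilar artery as a modified inlet waveform and quantifies how the ring
redistributes flow to the six cerebral outlet arteries, in the seconds
during and after the infarct.

## What it computes

The solver is a single-relaxation-time (BGK) lattice Boltzmann method on the
D3Q19 stencil. Nineteen mesoscopic populations `f_i` live on every fluid
voxel and evolve by collision and streaming,

    f_i(x + c_i, t + 1) = f_i(x, t) - (1/tau) [f_i(x, t) - f_i^eq(rho, u)],

with the second-order Maxwell–Boltzmann equilibrium
`f_i^eq = w_i rho (1 + 3 c_i.u + (9/2)(c_i.u)^2 - (3/2) u^2)`. Density and
momentum are moments of the populations; pressure is `c_s^2 rho` with
`c_s^2 = 1/3`; the kinematic viscosity is
`nu = c_s^2 (tau - 1/2) dx^2 / dt`, so whole blood
(`nu = 4.0e-6 m^2/s`) on a 25 µm / 1 µs lattice gives `tau = 0.5192`.
The scheme is valid in the low-Mach (incompressible) limit; a stability
diagnostic enforces a configurable Mach cap.

Around the kernel the package provides:

* **Parametric vessel networks** (capsule segments, axis-aligned inlet and
  outlet caps) voxelised to classified lattices, including an idealised
  circle of Willis with three inlets (basilar artery, left/right internal
  carotid arteries), six outlets (left/right posterior, middle and anterior
  cerebral arteries), and removable posterior communicating arteries — the
  two most relevant anatomical variants next to the complete ring.
* **Boundary conditions**: halfway bounce-back walls, prescribed-velocity
  inlets (moving-wall bounce-back, with a parabolic wall-distance weighting
  that reconstructs a Poiseuille profile on circular caps), and
  fixed-pressure outlets enforcing a zero normal pressure gradient.
* **Pulsatile waveforms and stroke scenarios**: a periodic systolic signal
  (three beats span 2.6 s) with a warm-up ramp, and five basilar-infarct
  envelopes — a sudden halt (complete within a quarter heartbeat), a linear
  stoppage to the simulation end, and linear restrictions to 50%, 30% and
  10% of healthy flow, all starting at the same onset.
* **Observables**: per-outlet volumetric flow-rate series,
  stroke-to-healthy flow ratios (window-smoothed and final-beat
  cycle-averaged), velocity-magnitude fields, and wall shear stress from
  the non-equilibrium stress tensor (clamped to 0–20 Pa for display
  exports).
* **Pipeline**: validated run configurations, deterministic compiled runs,
  healthy/stroke comparisons, the variant-by-scenario experiment matrix,
  grid-convergence studies, and an analytic validation suite (decaying
  shear wave, Poiseuille tube, planar Couette flow).

The compute kernel is C++ (via Rcpp); everything user-facing takes and
returns tibbles, with `tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

A sudden basilar-artery halt on the complete circle of Willis, at desk
scale (0.2 mm lattice, three heartbeats plus warm-up, about 15 s per run
on one core):

```r
library(willisflow)

# the reference discretisation reproduces the blood relaxation time
relaxation_time(4.0e-6, lattice_units(dx = 25e-6, dt = 1e-6))
#> [1] 0.5192

dom <- voxelize(build_idealized_cow("FULL"), dx = 2e-4)
dom
#> <voxel_domain> 144 x 134 x 59 grid, dx = 0.0002 m, 62428 wet sites (60828 fluid), 9 iolets

healthy <- run_simulation(cow_config("FULL", domain = dom))
stroke  <- run_simulation(cow_config("FULL", scenario = 1, domain = dom))
compare_runs(healthy, stroke)
#> <willis_comparison> final beat [2.13, 3] s
#> # A tibble: 6 × 3
#>   iolet ratio_final_beat  rank
#>   <chr>            <dbl> <int>
#> 1 RPCA             0.142     1
#> 2 LPCA             0.142     2
#> 3 RACA             0.973     3
#> 4 LACA             0.973     4
#> 5 LMCA             0.973     5
#> 6 RMCA             0.973     6
```

The `ratio_final_beat` column is each outlet's cycle-averaged flow over the
final heartbeat, relative to the healthy run. After the basilar inlet is
halted the two posterior cerebral arteries (PCAs) lose by far the most flow
— they are normally fed by the basilar artery and must now be supplied
through the narrow posterior communicating arteries — while the middle and
anterior cerebral arteries, fed directly by the carotids, barely change.
Repeating the experiment on the `NO_PCOA_LEFT` / `NO_PCOA_RIGHT` variants
(`run_matrix()`) deepens the ipsilateral PCA deficit further, since the
blocked side loses its rescue pathway. These directions mirror the clinical
picture for a posterior-circulation stroke; the exact percentages are
specific to the idealised geometry and the viscous desk-scale regime (see
the methods vignette).

`autoplot(compare_runs(healthy, stroke))` draws the ratio series per
outlet; `wss_field()` and `velocity_magnitude()` extract wall-shear-stress
and speed maps from snapshots, exportable with `export_field_nifti()`.

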