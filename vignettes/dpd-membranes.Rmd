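---
title: "Coarse-grained DPD simulation of phospholipid membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained DPD simulation of phospholipid membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dpdlipid)
```

## The model

`dpdlipid` implements dissipative particle dynamics (DPD) for phospholipid
membranes at a four-to-one coarse-graining: one bead stands for roughly four
heavy atoms, so a water bead carries `Nm = 4` water molecules. Matching bead
mass and volume to four waters fixes the reduced units at `r0 ≈ 0.71` nm and
`tau ≈ 143` ps, with `kBT = 1` referenced to 298 K. All internal quantities
are reduced; `to_physical()` converts at the I/O boundary.

Beads within the unit cutoff interact through three pairwise central forces:

* conservative soft repulsion `F_C = a_ij (1 - r) r_hat`,
* random force `F_R = sqrt(2 gamma_ij kBT) (1 - r) zeta_ij / sqrt(dt) r_hat`,
* dissipative force `F_D = -gamma_ij (1 - r)^2 (r_hat . v_ij) r_hat`.

The amplitude relation `sigma^2 = 2 gamma kBT` makes the random/dissipative
pair a momentum-conserving thermostat (fluctuation–dissipation balance). The
noise `zeta_ij` is uniform on `[-sqrt(3), sqrt(3)]` (zero mean, unit
variance), symmetric under `i <-> j`, and enters the discretized force with
the standard `1/sqrt(dt)` factor.

Bonded interactions are harmonic springs `E2 = K2 (r - L0)^2 / 2` and cosine
bending terms `E3 = K3 [1 - cos(theta - theta0)]`. Bonded pairs also feel
the nonbonded DPD repulsion, which is why the bond rest lengths (0.59 r0 for
tail bonds) sit below the fitted equilibrium separations.

### Bead types and force field

Five bead types are parameterized: water (W), choline (Q0), phosphate (Qa),
glycerol (Na) and hydrocarbon (C). The like-bead repulsion is 100 kBT/r0,
which reproduces the dimensionless water compressibility (~16 per molecule)
at density `rho = 3` through the equation of state
`P = rho T + alpha a rho^2` with `alpha ≈ 0.101`. Cross-type repulsions
(`default_forcefield()`) encode hydration and hydrophobicity:
head-group/water contacts are mildly attractive relative to water–water
(98), like-charge head beads repel more strongly (110) in lieu of explicit
electrostatics, and water–tail repulsion (130) corresponds to a
hydrocarbon–water Flory–Huggins chi of about 8. Friction coefficients come
in three tiers (4.5 / 9 / 20 for low / intermediate / high repulsion); the
tier boundaries `a <= 102`, `102 < a <= 110`, `a > 110` are a convention
chosen so each distinct repulsion in the table falls in exactly one tier,
and can be overridden in `friction_for()`.

### Lipid models

Lipids are h-shaped polymers (`lipid_template()`): a three-bead head group
(Q0–Qa–Na), a second glycerol bead attached by a short 0.31 r0 bond, and a
hydrocarbon tail on each glycerol. DMPC has three C beads per tail; DPPC has
four (two more CH2 groups per tail); DOPC has DPPC's bead count with the
angle ending at each terminal tail bead bent to 120 degrees to mimic chain
unsaturation. Backbone angles are straight (180 degrees, K3 = 6 kBT); bond
force constants are 512 kBT/r0^2. These constants are the Gaussian-fit
inversion `K = 4 kBT / w^2` of all-atom bond/angle distributions — the
fitting machinery itself is available as `fit_gaussian()`. Unstated DPPC and
DOPC bond parameters copy the DMPC tail values, and their head-group
geometry copies DMPC.

## Integration and ensembles

The equations of motion are advanced with the Groot–Warren modified
velocity-Verlet scheme at `dt = 0.02 tau`, with prediction parameter 0.5:
the dissipative force is evaluated with the half-kicked velocity after the
position update, then the velocity receives the corrector half-kick. The
scheme leaves a small positive kinetic-temperature offset — measured for
bulk water at `a = 100`, `dt = 0.02`: +1.1% at 3000 beads, +1.3% at 1536,
+1.9% at 648 — the known discretization artifact of DPD thermostats at
finite time step, largest in very small boxes; we document it rather than
re-tune the step.

Constant-pressure, zero-tension simulations (`ensemble = "npt"`) use a
semi-isotropic Langevin piston: one piston degree of freedom moves `Lz`
toward the normal-pressure target and a second moves `Lx = Ly` toward the
same tangential target, which enforces zero mean surface tension. Each
piston has inertia (default mass `500 m0`), damping (default `1 / tau`) and
thermal noise consistent with `T*`; the defaults relax a 128-lipid patch
from a strained start to its tensionless area within roughly 10^4 steps
(much heavier pistons track more smoothly but can take 10^5 steps to find
the tensionless area, which shows up as a residual apparent tension), and
both parameters are exposed. The virial pressure uses kinetic plus
conservative and bonded contributions only; dissipative and random terms
average to zero and are excluded, as is standard practice.

Randomness is counter-based: every noise draw is a hash of
(seed, step, pair). Runs are therefore reproducible from the seed alone,
restart exactly from a checkpoint (the step counter keys the stream), and
the cell-list and all-pairs force paths draw identical numbers. Pair
contributions are accumulated in sorted pair order so both paths agree
bitwise. Cell lists require at least three cells per axis; smaller boxes
fall back to the all-pairs path automatically.

## Observables

* `pressure_tensor()` / `surface_tension()`:
  `gamma_s = <Lz (Pzz - (Pxx + Pyy)/2)>`.
* `density_profile()`: per-type number densities along a box axis, either
  from stored frames or from the engine's in-loop histogram accumulator.
* `membrane_structure()`: thickness `l_mem` as the distance between mean
  choline (Q0) z positions of the two leaflets (leaflets assigned by which
  side of its own tail midpoint each head lies), and area per lipid
  `a0 = Lx Ly / (n/2)`.
* `chain_order()`: `S_chain = 0.5 <3 cos^2 theta - 1>` of the
  first-to-terminal tail-bead vector against the bilayer normal. The
  per-bond alternative definition changes the absolute value; the
  first-to-last convention is the default because it matches the reference
  values (~0.47 fluid DMPC, ~0.9 gel DPPC).
* `detect_rupture()`: water percolation across the membrane mid-plane
  (neighbour distance < 1 r0, band half-width 2 r0, both conventions
  exposed); transient percolation classifies as `"pore"`, sustained
  (>80% of frames) as `"ruptured"`.

## Calibrations

**Flory–Huggins slope.** `calibrate_chi()` runs the binary demixing
experiment: a pre-separated A/B slab at density 3 relaxes in the NVT
ensemble; the minority volume fraction `phi` over the homogeneous slab
interior gives `chi = ln[(1 - phi)/phi] / (1 - 2 phi)`, and the
zero-intercept fit of chi against the excess repulsion `delta_a` yields the
slope `lambda` used to translate chi values into repulsion parameters. At
the four-to-one mapping (like-bead repulsion 100) the slope is ~0.277;
at the one-molecule mapping (repulsion 25) ~0.298. Interfaces are located
at the `phi = 0.5` crossings of the composition profile and bins within
`d_excl = 2 r0` of an interface are excluded; the exclusion distance is a
convention (the interface width is ~1 r0) and is configurable. Excess
repulsions of 10–16 keep chi above 3, where demixed interiors are
homogeneous; weaker mismatches (chi < ~2.5) demix too weakly for a reliable
phi and are excluded from the fit with a warning.

**Equation of state.** `eos_scan()` measures bulk pressure at several
repulsion strengths and fits `alpha`; `fit_compressibility_alpha()` also
reports the implied dimensionless compressibility.

**Elasticity.** `fit_area_compressibility()` fits
`Sigma = K_A (a_prj - a0)/a0` inside a near-tensionless window
(default `|Sigma| <= 3 kBT/r0^2`), and `bending_rigidity()` applies
`kappa = K_A l_mem^2 / 48`. Applying this relation to the reference DMPC
numbers (`K_A = 23 kBT/r0^2`, `l_mem = 5.01 r0`) gives ~12 kBT, slightly
above the ~11 kBT quoted alongside them; we implement the relation
literally and note the small inconsistency of those rounded inputs.

**Flip-flop free energy.** `make_windows()` / `run_window()` /
`flipflop_pmf()` implement umbrella sampling on the phosphate bead of one
lipid: 61 windows spaced 0.15 r0 from the bilayer centre outward, force
constant 200 kBT/r0^2 (the force-constant unit is kBT/r0^2; pulls between
windows use 10 kBT/r0^2 over 10^4 steps, each window 5x10^4 equilibration
plus 5x10^4 production). The reaction coordinate is the z-offset from the
instantaneous lipid centre of mass, making the profile drift-invariant;
an absolute-z mode exists. Windows are generated sequentially, each pull
starting from the previous window's end state. `wham()` performs the
standard self-consistent histogram reweighting (bin width 0.05 r0, no
Jacobian for the 1-D Cartesian coordinate) and `pmf_barrier()` reports the
centre-minus-minimum cost.

## Numerical choices and degenerate inputs

* Angle forces use the cosine-potential gradient with a small-angle guard
  (`sin theta` floored at 1e-8); for straight equilibrium angles the
  coefficient reduces exactly to `-K3`, so the guard never activates on the
  dominant 180-degree terms.
* Beads closer than 1e-10 r0 exert no pair force on each other (the soft
  potential direction is undefined at contact); overlaps relax within a few
  steps.
* WHAM refuses non-overlapping adjacent windows, naming the gap; the PMF is
  reported only on bins with samples.
* The barostat signals box collapse when any edge shrinks below three
  cutoffs; builders refuse compositions inconsistent with density 3.

## What the built-in test systems do and do not show

The test suite exercises the full physics at reduced problem sizes chosen
to keep a complete run in minutes on one core: bulk boxes of 750–3000
beads, demixing slabs of 750+750 beads in 5 x 5 x 20 boxes with 3 x 10^4
steps, and a 128-lipid DMPC patch run for 10^5 zero-tension steps. At these
sizes the structural observables carry a few percent sampling error, which
is the tolerance the quantitative tests assert. The production-scale
protocols (1152-lipid bilayers, tension scans to rupture, vesicle
self-assembly from a free patch, the 61-window flip-flop profile, gel-phase
DPPC at `T* = 1`) use exactly the same code paths and are reachable through
the same functions and the command-line tool, but need hours of compute;
they are documented rather than asserted. Synthetic-data generators
(`fixture_generator()`) emulate demixed profiles with tanh interfaces and
umbrella samples from an exactly known quadratic surface; they validate the
estimators, not the dynamics — passing them says the analysis is correct,
not that the force field reproduces any particular real membrane.

## Known limitations

* No explicit electrostatics or polarizable water: head-group charge
  effects are folded into the repulsion table, so ion-specific or
  low-hydration phenomena are out of reach, and flip-flop PMFs lack the
  water-defect stabilization seen in all-atom simulations.
* The bending rigidity comes from the stretching relation, not from a
  fluctuation spectrum; it inherits the ~10% uncertainties of `K_A` and
  `l_mem`.
* One bead type per ~4 heavy atoms cannot resolve headgroup isomerism or
  chain-position-specific order parameters.
* The semi-isotropic barostat assumes the membrane normal is z; tilted or
  curved geometries (vesicles) should use NVT.
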