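# dpdlipid

Dissipative particle dynamics (DPD) simulation and analysis of
coarse-grained phospholipid membranes in R, built on a four-to-one mapping:
one simulation bead represents about four heavy atoms (a water bead carries
four water molecules), which fixes the reduced units at r0 ≈ 0.71 nm and
τ ≈ 143 ps. The package is aimed at membrane biophysicists and
methods developers who want a self-contained, reproducible DPD engine with
the full calibration and validation toolchain in one place.

## What it implements

**Force field.** Beads of five types (water W, choline Q0, phosphate Qa,
glycerol Na, hydrocarbon C) interact through soft conservative repulsion
F<sup>C</sup> = a<sub>ij</sub>(1 − r)r̂ inside a unit cutoff, plus pairwise
random and dissipative forces forming a momentum-conserving thermostat
(σ² = 2γk<sub>B</sub>T). Like-bead repulsion a = 100 k<sub>B</sub>T/r0
reproduces the water compressibility at bead density ρ = 3; unlike-bead
repulsions follow the Flory–Huggins route χ = λΔa, with the slope λ
calibrated by the package's own binary-demixing experiment. Lipids are
h-shaped bonded polymers (DMPC, DPPC, DOPC) with harmonic bonds
(K₂ = 512 k<sub>B</sub>T/r0²) and cosine bending angles (K₃ = 6 k<sub>B</sub>T).

**Engine.** Cell-list pair forces (bitwise-identical to the all-pairs
reference), Groot–Warren modified velocity Verlet (dt = 0.02 τ), NVT and
zero-tension constant-normal-pressure ensembles (semi-isotropic Langevin
piston), counter-based RNG for exact reproducibility and restart, all in
compiled code.

**Builders.** Bulk fluids, pre-separated binary slabs, planar bilayers
(two leaflet lattices, heads out, solvent filled to ρ = 3), and
free-standing patches for vesicle self-assembly.

**Observables and calibrations.** Pressure tensor and surface tension
γ<sub>s</sub> = ⟨L<sub>z</sub>(P<sub>z</sub> − (P<sub>x</sub>+P<sub>y</sub>)/2)⟩;
density profiles; membrane thickness and area per lipid; chain order
S<sub>chain</sub> = ½⟨3cos²θ − 1⟩; rupture detection by trans-membrane
water percolation; equation-of-state fit P = ρT + αaρ²; Flory–Huggins
χ = ln[(1−φ)/φ]/(1−2φ) from demixed slabs and the slope λ; elastic fits
Σ = K<sub>A</sub>(a<sub>prj</sub> − a₀)/a₀ and κ = K<sub>A</sub>l²/48;
Gaussian bond/angle fits K = 4k<sub>B</sub>T/w²; umbrella sampling with a
WHAM solver for lipid flip-flop free-energy profiles.

## Worked example

Measure the bulk pressure of DPD water and relax a small DMPC patch to its
tensionless state:

```r
library(dpdlipid)

## bulk water, a = 100, rho = 3, NVT
bp <- bulk_pressure(a_ii = 100, box = c(10, 10, 10),
                    steps_equil = 10000, steps_prod = 10000, seed = 1)
round(c(P = bp$P, T_kinetic = bp$temperature), 2)
#>         P T_kinetic
#>     89.01      1.01

## 128-lipid DMPC bilayer in the zero-tension ensemble
s  <- build_bilayer("DMPC", 128, a_prj = 1.30, seed = 5)
ff <- default_forcefield()
eq <- run_dpd(s, ff, steps = 20000, seed = 11, ensemble = "npt",
              p_target = 89, sample_stride = 100)
pr <- run_dpd(eq$state, ff, steps = 80000, seed = 11, ensemble = "npt",
              p_target = 89, sample_stride = 100, frame_stride = 4000)

ms <- membrane_structure(pr$frames)
round(c(l_mem_nm = ms$l_mem_nm, a0_nm2 = ms$a0_nm2,
        S_chain = chain_order(pr$frames)), 2)
#> l_mem_nm   a0_nm2  S_chain
#>     3.42     0.68     0.45
```

The pressure lands at ≈89 k<sub>B</sub>T/r0³ (the value used as the
barostat target for membranes), and the relaxed patch reproduces the
fluid-phase DMPC fingerprint — thickness 3.56 nm, area per lipid
0.66 nm², tail order 0.47 — to within the few-percent sampling error of a
128-lipid patch. A command-line wrapper with `build`, `run`, `analyze`,
`umbrella`, `wham`, `calibrate-chi` and `eos-scan` subcommands ships in
`inst/cli/dpdlipid`.

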