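Package: dpdlipid
Title: Dissipative Particle Dynamics Simulation of Phospholipid Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained dissipative particle dynamics (DPD) engine and
    analysis toolkit for coarse-grained phospholipid membranes built on a
    four-to-one heavy-atom mapping. Provides the five-bead-type force field
    with its Flory-Huggins chi-parameter calibration, h-shape DMPC/DPPC/DOPC
    lipid models, system builders for bulk fluids, binary demixing slabs,
    planar bilayers and vesicle-formation starts, NVT and zero-tension
    constant-normal-pressure ensembles (Langevin piston), and the structural,
    elastic and free-energy observables used to validate such models:
    density profiles, surface tension, membrane thickness, area per lipid,
    chain order, area compressibility and bending rigidity, equation-of-state
    and chi-slope calibrations, umbrella sampling and WHAM potentials of
    mean force for lipid flip-flop.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
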