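test_that("default repulsion table has the published entries and symmetry", {
  ff <- default_forcefield()
  a <- ff$repulsion
  expect_identical(dim(a), c(5L, 5L))
  # like-bead repulsion is 100 except for the charged head beads, whose
  # self-repulsion is raised to 110 in lieu of explicit electrostatics
  expect_equal(unname(diag(a)), c(100, 110, 110, 100, 100))
  expect_identical(a, t(a))
  expect_equal(a["W", "W"], 100)
  expect_equal(a["W", "Q0"], 98)
  expect_equal(a["W", "Qa"], 98)
  expect_equal(a["W", "Na"], 102)
  expect_equal(a["W", "C"], 130)
  expect_equal(a["Q0", "Qa"], 100)
  expect_equal(a["Q0", "Q0"], 110)
  expect_equal(a["Na", "C"], 110)
  expect_equal(a["Qa", "C"], 130)
})

test_that("friction tiers map every repulsion in the table to 4.5, 9 or 20", {
  expect_equal(friction_for(100), 4.5)
  expect_equal(friction_for(110), 9)
  expect_equal(friction_for(130), 20)
  ff <- default_forcefield()
  expect_true(all(ff$friction %in% c(4.5, 9, 20)))
  expect_identical(ff$friction, t(ff$friction))
  # low-repulsion entries (98, 100, 102) all sit in the 4.5 tier
  expect_equal(unname(friction_for(c(98, 102))), c(4.5, 4.5))
  expect_error(friction_for(0), "positive")
  expect_error(friction_for(-3), "positive")
})

test_that("lipid templates encode the h-shape bonded tables", {
  dmpc <- lipid_template("DMPC")
  expect_length(dmpc$bead_types, 10)
  expect_identical(dmpc$bead_types,
                   c("Q0", "Qa", "Na", "C", "C", "C", "Na", "C", "C", "C"))
  expect_equal(nrow(dmpc$bonds), 9)
  expect_equal(nrow(dmpc$angles), 6)
  b37 <- dmpc$bonds[dmpc$bonds$i == 3 & dmpc$bonds$j == 7, ]
  expect_equal(b37$L0, 0.31)
  b12 <- dmpc$bonds[dmpc$bonds$i == 1 & dmpc$bonds$j == 2, ]
  expect_equal(b12$L0, 0.47)
  expect_equal(b12$K2, 512)
  expect_true(all(dmpc$bonds$K2 == 512))
  expect_true(all(dmpc$angles$K3 == 6))
  # glycerol branch angle is the only bent one in DMPC
  bent <- dmpc$angles[dmpc$angles$theta0 == 120, ]
  expect_equal(nrow(bent), 1)
  expect_equal(c(bent$i, bent$j, bent$k), c(2, 3, 7))

  water <- lipid_template("WATER")
  expect_length(water$bead_types, 1)
  expect_equal(nrow(water$bonds), 0)

  dppc <- lipid_template("DPPC")
  expect_length(dppc$bead_types, 12)
  expect_equal(sum(dppc$bead_types == "C"), 8)
  expect_true(all(dppc$angles$theta0 %in% c(120, 180)))
  expect_equal(sum(dppc$angles$theta0 == 120), 1) # only the branch

  dopc <- lipid_template("DOPC")
  expect_length(dopc$bead_types, 12)
  # branch plus the two terminal-tail kinks
  expect_equal(sum(dopc$angles$theta0 == 120), 3)
  expect_error(lipid_template("POPC"))
})

test_that("unit conversions match the four-to-one mapping constants", {
  expect_equal(to_physical(1, "length"), 0.71)
  expect_equal(to_physical(1.30, "area"), 0.655, tolerance = 1e-3)
  expect_equal(to_physical(1, "time"), 143)
  expect_equal(to_physical(0, "energy"), 0)
  # K_A = 23 kBT/r0^2 is ~188 mN/m (the dyn/cm conversion used for membranes)
  expect_equal(to_physical(23, "tension"), 188, tolerance = 0.01)
  # 16 kBT is ~40 kJ/mol
  expect_equal(to_physical(16, "energy_kJmol"), 39.7, tolerance = 0.01)
  x <- c(0.3, 1.7, 42)
  for (kind in c("length", "area", "time", "energy", "tension")) {
    expect_equal(from_physical(to_physical(x, kind), kind), x)
  }
  expect_error(to_physical(1, "volume"), "unknown")
})

test_that("force field round-trips through the text config", {
  ff <- default_forcefield()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_forcefield(ff, path)
  ff2 <- read_forcefield(path)
  expect_equal(ff2$repulsion, ff$repulsion)
  expect_equal(ff2$friction, ff$friction)
  expect_equal(ff2$temperature, ff$temperature)
  expect_equal(ff2$units$r0_nm, ff$units$r0_nm)
})

test_that("packaged default force-field file matches the in-code default", {
  path <- system.file("extdata", "forcefield_nm4.yaml", package = "dpdlipid")
  expect_true(nzchar(path))
  ff <- read_forcefield(path)
  expect_equal(ff$repulsion, default_forcefield()$repulsion)
})

test_that("constructor rejects asymmetric or non-positive tables", {
  m <- matrix(c(100, 90, 80, 100), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(forcefield(m), "symmetric")
  m2 <- matrix(c(100, -5, -5, 100), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(forcefield(m2), "positive")
})
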