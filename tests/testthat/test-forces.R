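# Pairwise and bonded force evaluation.

test_that("conservative pair force is a(1 - r) inside the cutoff, zero outside", {
  box <- c(6, 6, 6)
  # two beads along x at r = 0.5, zero velocity, negligible friction
  st <- free_state(rbind(c(1, 1, 1), c(1.5, 1, 1)), box)
  ff <- water_ff(a = 100, gamma = 1e-300)
  f <- compute_forces(st, ff)
  expect_equal(f$forces[1, 1], -50, tolerance = 1e-12)
  expect_equal(f$forces[2, 1], 50, tolerance = 1e-12)
  expect_equal(f$forces[, 2:3], matrix(0, 2, 2))

  # W-C pair at r = 0.5 with the default table: |F_C| = 130 * 0.5 = 65
  st2 <- free_state(rbind(c(1, 1, 1), c(1.5, 1, 1)), box,
                    labels = c("W", "C"), type = c(1L, 2L))
  ffwc <- forcefield(default_forcefield()$repulsion[c("W", "C"), c("W", "C")],
                     friction = matrix(1e-300, 2, 2,
                                       dimnames = list(c("W", "C"), c("W", "C"))))
  f2 <- compute_forces(st2, ffwc)
  expect_equal(abs(f2$forces[1, 1]), 65, tolerance = 1e-10)

  # beyond the cutoff all three force components vanish identically
  st3 <- free_state(rbind(c(1, 1, 1), c(2.2, 1, 1)), box,
                    vel = rbind(c(1, 0, 0), c(-1, 0, 0)))
  f3 <- compute_forces(st3, water_ff())
  expect_identical(unname(f3$forces), matrix(0, 2, 3))
  expect_equal(f3$n_pairs, 0)
})

test_that("random and dissipative forces are central and pairwise antisymmetric", {
  set.seed(4)
  st <- free_state(matrix(runif(60, 0, 4), 20, 3), c(4, 4, 4),
                   vel = matrix(rnorm(60), 20, 3))
  f <- compute_forces(st, water_ff(), seed = 9, step = 3)
  # Newton's third law: net force is zero to machine precision
  expect_lt(max(abs(colSums(f$forces))), 1e-10)
  # same (seed, step) reproduces the same random forces
  f2 <- compute_forces(st, water_ff(), seed = 9, step = 3)
  expect_identical(f$forces, f2$forces)
  # a different step draws different noise
  f3 <- compute_forces(st, water_ff(), seed = 9, step = 4)
  expect_false(identical(f$forces, f3$forces))
})

test_that("bond force is K2 * extension at the minimum-plus-offset geometry", {
  tpl <- list(name = "DIMER", bead_types = c("W", "W"),
              bonds = data.frame(i = 1, j = 2, L0 = 0.59, K2 = 512),
              angles = dpdlipid:::empty_angles())
  class(tpl) <- "dpd_template"
  box <- c(6, 6, 6)
  # at r = L0 the bond force vanishes
  st0 <- molecule_state(tpl, rbind(c(1, 1, 1), c(1.59, 1, 1)), box)
  st0$type <- c(1L, 1L); st0$type_labels <- "W"
  f0 <- compute_forces(st0, water_ff(a = 1e-300, gamma = 1e-300))
  expect_lt(max(abs(f0$forces)), 1e-10)
  # stretched by 0.1: |F| = 51.2
  st1 <- molecule_state(tpl, rbind(c(1, 1, 1), c(1.69, 1, 1)), box)
  st1$type <- c(1L, 1L); st1$type_labels <- "W"
  f1 <- compute_forces(st1, water_ff(a = 1e-300, gamma = 1e-300))
  expect_equal(f1$forces[1, 1], 51.2, tolerance = 1e-10)
  expect_equal(f1$forces[2, 1], -51.2, tolerance = 1e-10)
})

test_that("angle force vanishes at the equilibrium angle and balances", {
  tpl <- lipid_template("DMPC")
  # straight 3-4-5 angle (theta0 = 180): collinear tail gives zero torque
  pos <- cbind(2 + dpdlipid:::lipid_depths(tpl), 2, 2)
  st <- molecule_state(tpl, pos, c(8, 8, 8))
  f <- compute_forces(st, bonded_only_ff())
  # bonds are at rest length along the chain backbone and angles straight
  # except the built-in 120-degree branch, so forces appear only around the
  # branch beads (2, 3, 7); the 4-5-6 and 8-9-10 tails stay force-free
  expect_lt(max(abs(f$forces[c(5, 6, 9, 10), ])), 1e-8)
  expect_lt(max(abs(colSums(f$forces))), 1e-9)
})

test_that("bonded forces are the exact negative gradient of the energy", {
  set.seed(11)
  tpl <- lipid_template("DOPC") # includes bent terminal angles
  base <- cbind(2 + dpdlipid:::lipid_depths(tpl), 4, 4)
  pos <- base + matrix(rnorm(length(base), sd = 0.15), ncol = 3)
  st <- molecule_state(tpl, pos, c(10, 10, 10))
  f <- compute_forces(st, bonded_only_ff())$forces
  h <- 1e-6
  for (b in c(1, 3, 7, 12)) {
    for (k in 1:3) {
      sp <- st; sm <- st
      sp$pos[b, k] <- sp$pos[b, k] + h
      sm$pos[b, k] <- sm$pos[b, k] - h
      num <- -(bonded_energy(sp) - bonded_energy(sm)) / (2 * h)
      expect_equal(f[b, k], num, tolerance = 1e-5)
    }
  }
})

test_that("pressure tensor reproduces the ideal-gas and static limits", {
  # static sparse lattice, v = 0, no pairs within the cutoff: P = 0
  g <- expand.grid(x = seq(0.75, 5.25, 1.5), y = seq(0.75, 5.25, 1.5),
                   z = seq(0.75, 5.25, 1.5))
  st <- free_state(as.matrix(g), c(6, 6, 6))
  p <- pressure_tensor(st, water_ff())
  expect_equal(unname(p), c(0, 0, 0))

  # near-ideal gas (vanishing repulsion): P = rho T from the kinetic term
  set.seed(2)
  n <- 648
  st2 <- free_state(matrix(runif(3 * n, 0, 6), n, 3), c(6, 6, 6),
                    vel = matrix(rnorm(3 * n), n, 3))
  p2 <- pressure_tensor(st2, water_ff(a = 1e-300, gamma = 1e-300))
  expect_equal(mean(p2), 3, tolerance = 0.1)
})
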