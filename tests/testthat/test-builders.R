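# Initial-configuration builders.

test_that("bulk builder matches density, momentum and determinism contracts", {
  s <- build_bulk(c(10, 10, 10), seed = 1)
  expect_equal(nrow(s$pos), 3000)
  expect_equal(unname(total_momentum(s)), c(0, 0, 0), tolerance = 1e-12)
  expect_true(all(s$pos >= 0 & s$pos <= rep(s$box, each = nrow(s$pos))))
  s2 <- build_bulk(c(10, 10, 10), seed = 1)
  expect_identical(s$pos, s2$pos)
  expect_identical(s$vel, s2$vel)
  expect_error(build_bulk(c(5, 5, 5), c(W = 100)), "density")
})

test_that("bulk water density is homogeneous after brief equilibration", {
  s <- build_bulk(c(6, 6, 6), seed = 2)
  out <- run_dpd(s, water_ff(), steps = 1000, seed = 2, sample_stride = 0)
  # time-average 2x2x2 bins of 27 r0^3 over a short trajectory
  acc <- numeric(8)
  nf <- 10
  st <- out$state
  for (f in seq_len(nf)) {
    st <- run_dpd(st, water_ff(), steps = 100, seed = 2, sample_stride = 0)$state
    p <- st$pos
    bin <- floor(p[, 1] / 3) + 2 * floor(p[, 2] / 3) + 4 * floor(p[, 3] / 3)
    acc <- acc + tabulate(bin + 1, 8) / 27
  }
  expect_true(all(abs(acc / nf - 3) / 3 < 0.05))
})

test_that("binary slab builder pre-separates the phases", {
  s <- build_binary_slab(3000, 3000, c(10, 10, 20), seed = 4)
  expect_equal(nrow(s$pos), 6000)
  A <- s$type == 1
  expect_gt(mean(s$pos[A, 3]), 10)
  expect_lt(mean(s$pos[!A, 3]), 10)
  expect_true(all(s$pos[, 3] >= 0 & s$pos[, 3] <= 20))
  # scaled recipe
  s2 <- build_binary_slab(375, 375, c(5, 5, 10), seed = 4)
  expect_equal(nrow(s2$pos), 750)
  expect_error(build_binary_slab(300, 300, c(5, 5, 10)), "requires")
})

test_that("bilayer builder obeys the area/box/topology relations", {
  s <- build_bilayer("DMPC", 1152, a_prj = 1.30, seed = 1)
  expect_equal(s$box[1], sqrt(1152 * 1.30 / 2), tolerance = 1e-12)
  expect_equal(s$box[1], 27.4, tolerance = 0.01)
  lipid_beads <- sum(s$species[s$mol_id] == "DMPC")
  expect_equal(lipid_beads, 11520)
  expect_equal(nrow(s$bonds), 9 * 1152)
  expect_equal(nrow(s$angles), 6 * 1152)
  n_w <- sum(s$type_labels[s$type] == "W")
  expect_equal(lipid_beads + n_w, round(3 * prod(s$box)))
  expect_equal(unname(total_momentum(s)), c(0, 0, 0), tolerance = 1e-12)
  # no water starts inside the membrane slab
  wz <- s$pos[s$type_labels[s$type] == "W", 3]
  expect_true(all(abs(wz - s$box[3] / 2) >= 3))

  # a scaled patch obeys the same relations
  s128 <- build_bilayer("DMPC", 128, a_prj = 1.25, seed = 2)
  expect_equal(s128$box[1], sqrt(128 * 1.25 / 2), tolerance = 1e-12)
  expect_equal(nrow(s128$bonds), 9 * 128)
  expect_error(build_bilayer("DMPC", 33))
})

test_that("vesicle start embeds the patch away from its periodic images", {
  s <- build_vesicle_start("DMPC", 128, a_prj = 1.30, margin = 12, seed = 3)
  patch_side <- sqrt(128 * 1.30 / 2)
  expect_equal(s$box[1], patch_side + 12, tolerance = 1e-12)
  lipid <- s$species[s$mol_id] == "DMPC"
  xy <- s$pos[lipid, 1:2]
  gap_x <- s$box[1] - (max(xy[, 1]) - min(xy[, 1]))
  gap_y <- s$box[2] - (max(xy[, 2]) - min(xy[, 2]))
  expect_gt(min(gap_x, gap_y), 10)
  expect_equal(nrow(s$pos), round(3 * prod(s$box)))
  s2 <- build_vesicle_start("DMPC", 128, a_prj = 1.30, margin = 12, seed = 3)
  expect_identical(s$pos, s2$pos)
})
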