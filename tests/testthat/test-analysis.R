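# Observables and fitters.

test_that("surface tension is the height-weighted normal-tangential difference", {
  df <- data.frame(Pxx = 88, Pyy = 88, Pzz = 90, Lz = 24)
  expect_equal(surface_tension(df), 48)
  # isotropic samples average to zero
  set.seed(1)
  iso <- data.frame(Pxx = rnorm(200, 89, 1), Pyy = rnorm(200, 89, 1),
                    Pzz = rnorm(200, 89, 1), Lz = 10)
  gs <- surface_tension(iso)
  expect_lt(abs(gs), 3 * attr(gs, "se"))
})

test_that("density profile is flat for bulk and conserves bead counts", {
  set.seed(6)
  n <- 3000
  st <- free_state(matrix(runif(3 * n, 0, 10), n, 3), c(10, 10, 10))
  prof <- density_profile(st, n_bins = 10)
  expect_equal(unname(prof$total), rep(3, 10), tolerance = 0.15)
  # integral over the box returns the bead count
  expect_equal(sum(prof$density) * 100 * prof$bin_width, n)
  # per-type densities sum to the total
  expect_equal(colSums(prof$density), prof$total)
  expect_error(density_profile(st, n_bins = 5), "n_bins")
})

test_that("membrane structure recovers a synthetic two-plane geometry", {
  st <- toy_bilayer_state(head_z = 2.5, n_side = 2, box = c(6, 6, 12))
  ms <- membrane_structure(st)
  expect_equal(ms$l_mem, 5.0, tolerance = 1e-12)
  expect_equal(ms$a0, 6 * 6 / 4, tolerance = 1e-12)
  expect_equal(ms$l_mem_nm, 5.0 * 0.71, tolerance = 1e-12)
  # area per lipid at the production geometry: Lx = Ly = 27.4, 1152 lipids
  expect_equal(27.4^2 / 576, 1.30, tolerance = 0.01)
})

test_that("chain order hits the aligned, in-plane and isotropic limits", {
  st <- toy_bilayer_state() # tails exactly along z
  expect_equal(chain_order(st), 1, tolerance = 1e-12)

  # in-plane chains: rotate tails into the x axis
  st2 <- toy_bilayer_state()
  tpl <- lipid_template("DMPC")
  nb <- length(tpl$bead_types)
  for (m in unique(st2$mol_id[st2$species[st2$mol_id] == "DMPC"])) {
    rows <- which(st2$mol_id == m)
    z <- st2$pos[rows, 3]
    st2$pos[rows, 1] <- st2$pos[rows, 1] + (z - z[1])
    st2$pos[rows, 3] <- z[1]
  }
  expect_equal(chain_order(st2), -0.5, tolerance = 1e-12)

  # isotropic orientations average to zero (Monte-Carlo oracle)
  set.seed(9)
  u <- matrix(rnorm(3 * 20000), ncol = 3)
  cos2 <- (u[, 3]^2) / rowSums(u^2)
  s_iso <- mean(0.5 * (3 * cos2 - 1))
  expect_lt(abs(s_iso), 3 / sqrt(20000) * 2)
})

test_that("chi closed form, limit and round trip are exact", {
  expect_equal(chi_for_phi(0.2), log(4) / 0.6, tolerance = 1e-12)
  expect_equal(chi_for_phi(0.2), 2.3105, tolerance = 1e-4)
  expect_equal(chi_for_phi(0.5), 2) # L'Hopital limit
  # analytic round trip over the working range
  for (chi in seq(2.5, 6, by = 0.5)) {
    phi <- dpdlipid:::phi_for_chi(chi)
    expect_equal(chi_for_phi(phi), chi, tolerance = 1e-6)
  }
})

test_that("chi_from_profile reads phi off a synthetic demixed profile", {
  for (phi_true in c(0.05, 0.1, 0.2)) {
    prof <- fixture_generator("synthetic_profile", phi = phi_true)
    chi <- chi_from_profile(prof)
    expect_equal(attr(chi, "phi"), phi_true, tolerance = 0.01)
    expect_equal(as.numeric(chi), chi_for_phi(phi_true), tolerance = 0.05)
  }
  # mixed profile: chi undefined
  mixed <- dpdlipid:::new_profile(seq(0.25, 19.75, 0.5),
                                  rbind(A = rep(1.5, 40), B = rep(1.5, 40)),
                                  "z", 0.5)
  expect_warning(chi <- chi_from_profile(mixed), "no demixing")
  expect_true(is.na(chi))
})

test_that("lambda fit recovers exact slopes and flags non-demixed points", {
  d <- c(10, 13, 16)
  fit <- fit_lambda(d, 0.277 * d)
  expect_equal(fit$lambda, 0.277, tolerance = 1e-12)
  expect_lt(fit$se, 1e-12)
  expect_warning(fit2 <- fit_lambda(c(2, d), c(NA, 0.3 * d)), "non-demixed")
  expect_equal(fit2$lambda, 0.3, tolerance = 1e-12)
})

test_that("equation-of-state fitter is exact on synthetic data", {
  a <- c(25, 50, 100)
  tab <- data.frame(a = a, rho = 3, P = 3 + 0.101 * a * 9)
  fit <- fit_compressibility_alpha(tab)
  expect_equal(fit$alpha, 0.101, tolerance = 1e-12)
  k <- fit$k_inv(100, 3)
  expect_equal(k$k_inv, 61.6, tolerance = 1e-10)
  expect_equal(k$k_inv_per_molecule, 15.4, tolerance = 1e-10)
  # a = 0 is the ideal gas: P = rho T exactly, zero excess
  tab0 <- data.frame(a = c(0, 50), rho = 3, P = c(3, 3 + 0.1 * 50 * 9))
  expect_equal(fit_compressibility_alpha(tab0)$alpha, 0.1, tolerance = 1e-12)
})

test_that("area-compressibility fit recovers the elastic line", {
  a0 <- 1.30; KA <- 23
  a_prj <- seq(1.2, 1.45, by = 0.05)
  Sigma <- KA * (a_prj - a0) / a0
  fit <- fit_area_compressibility(a_prj, Sigma)
  expect_equal(fit$K_A, KA, tolerance = 1e-9)
  expect_equal(fit$a0, a0, tolerance = 1e-9)
  # tension vanishes at the fitted tensionless area by construction
  expect_equal(KA * (fit$a0 - a0) / a0, 0, tolerance = 1e-9)
  # noisy synthetic: recovered within 10% (regression oracle)
  set.seed(3)
  fitn <- fit_area_compressibility(a_prj, Sigma + rnorm(length(Sigma), sd = 0.1))
  expect_equal(fitn$K_A, KA, tolerance = 0.1)
  expect_warning(fit_area_compressibility(c(1.4, 1.5, 1.6),
                                          c(1.8, 3.5, 5.3) / 1),
                 "sign change")
})

test_that("bending rigidity follows the K_A l^2 / 48 relation", {
  expect_equal(bending_rigidity(48, 1)$kappa, 1)
  k <- bending_rigidity(23, 3.56 / 0.71)
  expect_equal(k$kappa, 23 * (3.56 / 0.71)^2 / 48, tolerance = 1e-12)
  expect_equal(k$kappa, 12.0, tolerance = 0.05)
  expect_equal(k$kappa_J, k$kappa * 1.380649e-23 * 298.15, tolerance = 1e-12)
})

test_that("gaussian fitter inverts the harmonic force constants", {
  # noise-free histogram of the bond-length distribution for K2 = 512
  w_true <- sqrt(4 / 512)
  mids <- seq(0.47 - 0.4, 0.47 + 0.4, length.out = 161)
  y <- 1000 / (w_true * sqrt(pi / 2)) * exp(-2 * (mids - 0.47)^2 / w_true^2)
  bin_w <- mids[2] - mids[1]
  fit <- fit_gaussian(mids, counts = y * bin_w)
  expect_equal(fit$center, 0.47, tolerance = 1e-6)
  expect_equal(fit$width, w_true, tolerance = 1e-6)
  expect_equal(fit$K, 512, tolerance = 1e-3)
  expect_equal(fit$area, 1000, tolerance = 1e-3)

  # angle-center recovery from sampled data near 174 degrees
  set.seed(12)
  th <- rnorm(20000, 174, 4)
  fita <- fit_gaussian(th, n_bins = 60)
  expect_equal(fita$center, 174, tolerance = 0.5)
  # area equals sample count (integral of the fitted density)
  expect_equal(fita$area, 20000, tolerance = 0.02 * 20000)
})

test_that("rupture detector classifies intact, pierced and degenerate systems", {
  st <- toy_bilayer_state(head_z = 2.5, n_side = 3, box = c(6, 6, 12))
  # add bulk water far from the membrane: still intact
  nw <- 60
  set.seed(8)
  wpos <- cbind(runif(nw, 0, 6), runif(nw, 0, 6),
                sample(c(runif(nw / 2, 0, 2), runif(nw / 2, 10, 12))))
  intact <- append_water(st, wpos)
  expect_equal(detect_rupture(intact), "intact")

  # a water column piercing the mid-plane forms a pore
  col <- cbind(3, 3, seq(3, 9, by = 0.5))
  pierced <- append_water(intact, col)
  expect_equal(detect_rupture(pierced), "ruptured") # single frame, sustained
  expect_true(dpdlipid:::frame_percolates(pierced))

  # a transient pore (pierced in some frames only) is classified as "pore"
  healed <- pierced
  col_rows <- (nrow(pierced$pos) - nrow(col) + 1):nrow(pierced$pos)
  healed$pos[col_rows, 3] <- 1
  expect_equal(detect_rupture(list(pierced, healed, healed)), "pore")

  # bulk water without a membrane is flagged as degenerate
  bulk <- build_bulk(c(5, 5, 5), seed = 1)
  expect_equal(detect_rupture(bulk), "ruptured")
})
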