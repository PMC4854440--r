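# Umbrella windows and the WHAM solver.

test_that("window generation spans the flip-flop coordinate", {
  w <- make_windows()
  expect_equal(nrow(w), 61)
  expect_equal(w$zstar[1], 0)
  expect_equal(max(w$zstar), 9.0)
  expect_equal(diff(w$zstar)[1], 0.15)
  expect_true(all(w$k == 200))
  w2 <- make_windows(n = 11, spacing = 0.3, k = 50)
  expect_equal(max(w2$zstar), (11 - 1) * 0.3)
  expect_error(make_windows(n = 1))
})

test_that("single unbiased window reduces WHAM to a histogram inversion", {
  set.seed(2)
  x <- rnorm(20000, 1, 0.5)
  res <- wham(list(list(zstar = 0, k = 0, samples = x)), bin_width = 0.1)
  ok <- is.finite(res$pmf)
  ref <- -log(dnorm(res$grid[ok], 1, 0.5))
  ref <- ref - min(ref)
  # agreement away from the sparsely sampled tails
  core <- abs(res$grid[ok] - 1) < 1
  expect_lt(sqrt(mean((res$pmf[ok][core] - ref[core])^2)), 0.1)
})

test_that("WHAM reconstructs a known quadratic free-energy surface", {
  wins <- fixture_generator("synthetic_pmf_samples", seed = 21,
                            c_quad = 2, n_windows = 10, spacing = 0.3,
                            k = 20, n_samples = 4000)
  true_pmf <- attr(wins, "true_pmf")
  res <- wham(wins, bin_width = 0.05)
  ok <- is.finite(res$pmf)
  grid <- res$grid[ok]
  ref <- true_pmf(grid) - min(true_pmf(grid))
  # compare over the well-sampled range covered by the windows
  core <- grid > -0.2 & grid < 2.9
  rms <- sqrt(mean((res$pmf[ok][core] - ref[core])^2))
  expect_lt(rms, 0.2)

  # bin-width halving changes the well-sampled part by less than 0.1 kBT
  res2 <- wham(wins, bin_width = 0.025)
  well <- grid > 0 & grid < 2.5
  al <- approx(res2$grid, res2$pmf, xout = grid[well])$y
  expect_lt(max(abs(al - res$pmf[ok][well]), na.rm = TRUE), 0.1)

  # permuting the window order leaves the profile unchanged
  res3 <- wham(rev(wins), bin_width = 0.05)
  expect_equal(res3$pmf, res$pmf, tolerance = 1e-8)
})

test_that("non-overlapping adjacent windows raise an error naming the gap", {
  set.seed(5)
  wins <- list(list(zstar = 0, k = 200, samples = rnorm(500, 0, 0.05)),
               list(zstar = 5, k = 200, samples = rnorm(500, 5, 0.05)))
  expect_error(wham(wins), "non-overlapping")
})

test_that("barrier extraction finds the minimum and centre cost", {
  grid <- seq(-0.5, 4, by = 0.05)
  pmf <- (grid - 2.5)^2 * 2
  obj <- structure(list(grid = grid, pmf = pmf - min(pmf), iterations = 0,
                        residual = 0, overlap = NULL,
                        window_free_energies = NULL), class = "dpd_pmf")
  b <- pmf_barrier(obj)
  expect_equal(b$z_min, 2.5, tolerance = 0.05)
  expect_equal(b$barrier, 2 * 2.5^2, tolerance = 0.05)
  expect_equal(b$barrier_kJmol, b$barrier * 2.478, tolerance = 0.01 * b$barrier)
  # a quadratic referenced at its minimum at the centre has zero barrier
  obj0 <- structure(list(grid = grid, pmf = 2 * grid^2), class = "dpd_pmf")
  expect_warning(b0 <- pmf_barrier(obj0), NA) # interior minimum, no warning
  expect_equal(b0$barrier, 0, tolerance = 1e-9)
  # minimum on the edge warns about coverage
  objE <- structure(list(grid = grid, pmf = grid + 0.5), class = "dpd_pmf")
  expect_warning(pmf_barrier(objE), "edge")
})
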