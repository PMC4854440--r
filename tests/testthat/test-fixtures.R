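test_that("fixtures are deterministic and correctly sized", {
  b1 <- fixture_generator("bulk64", seed = 7)
  b2 <- fixture_generator("bulk64", seed = 7)
  expect_identical(b1$pos, b2$pos)
  expect_equal(nrow(b1$pos), 64)

  s <- fixture_generator("slab750", seed = 1)
  expect_equal(nrow(s$pos), 750)
  expect_equal(s$box, c(5, 5, 10))

  bl <- fixture_generator("bilayer32", seed = 2)
  expect_equal(sum(bl$species[bl$mol_id] == "DMPC") / 10, 32)
  expect_equal(bl$box[1], sqrt(32 * 1.3 / 2), tolerance = 1e-12)
  expect_equal(bl$box[3], 24)

  w1 <- fixture_generator("synthetic_pmf_samples", seed = 3)
  w2 <- fixture_generator("synthetic_pmf_samples", seed = 3)
  expect_identical(w1[[1]]$samples, w2[[1]]$samples)
  expect_true(is.function(attr(w1, "true_pmf")))
})

test_that("command-line interface builds, runs and analyzes a tiny system", {
  dir <- withr::local_tempdir()
  cfg <- run_config(recipe = list(kind = "bilayer", species = "DMPC",
                                  n_lipids = 8, a_prj = 1.3, Lz = 12),
                    n_steps = 100, seed = 3, sample_stride = 10,
                    frame_stride = 50)
  cfg_path <- file.path(dir, "run.yaml")
  write_config(cfg, cfg_path)
  chk <- file.path(dir, "sys.chk")
  expect_equal(suppressMessages(
    dpd_cli(c("build", "--config", cfg_path, "--out", chk))), 0L)
  expect_true(file.exists(chk))
  final <- file.path(dir, "final.chk")
  traj <- file.path(dir, "run.xyz")
  expect_equal(suppressMessages(
    dpd_cli(c("run", "--config", cfg_path, "--in", chk, "--out", final,
              "--traj", traj))), 0L)
  expect_true(file.exists(final) && file.exists(traj))
  report <- file.path(dir, "report.tsv")
  expect_equal(suppressMessages(
    dpd_cli(c("analyze", "--traj", traj, "--topology", paste0(chk, ".top"),
              "--out", report))), 0L)
  tab <- read.delim(report)
  expect_true("l_mem" %in% tab$observable)
  # zero steps returns the initial state unchanged
  cfg0 <- cfg; cfg0$n_steps <- 0
  write_config(cfg0, cfg_path)
  out0 <- run_from_config(read_config(cfg_path),
                          state = read_checkpoint(chk))
  expect_identical(out0$state$pos, read_checkpoint(chk)$pos)
  # invalid input is a nonzero exit, not an R error
  expect_equal(suppressMessages(dpd_cli(c("frobnicate"))), 1L)
  expect_equal(suppressMessages(dpd_cli(character(0))), 1L)
})

test_that("wham subcommand reconstructs a PMF from window files", {
  dir <- withr::local_tempdir()
  wins <- fixture_generator("synthetic_pmf_samples", seed = 4, n_windows = 6,
                            n_samples = 1500)
  for (i in seq_along(wins)) {
    writeLines(c(sprintf("# zstar %g k %g", wins[[i]]$zstar, wins[[i]]$k),
                 sprintf("%.10g", wins[[i]]$samples)),
               file.path(dir, sprintf("window_%03d.dat", i - 1)))
  }
  out <- file.path(dir, "pmf.tsv")
  expect_equal(suppressMessages(
    dpd_cli(c("wham", "--windows", dir, "--out", out))), 0L)
  tab <- read.delim(out)
  expect_true(all(c("z", "pmf_kBT") %in% names(tab)))
  expect_gt(nrow(tab), 10)
})
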