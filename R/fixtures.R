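# Deterministic miniature systems and synthetic arrays for testing and
# examples.

#' Generate small deterministic test systems
#'
#' * `bulk64`: 64 water beads at density 3 (box ~2.77^3).
#' * `slab750`: pre-separated 375 + 375 A/B slab in a 5 x 5 x 10 box.
#' * `bilayer32`: 32 DMPC lipids plus water in a ~4.6 x 4.6 x 24 box.
#' * `synthetic_profile`: an analytic demixed composition profile with a
#'   known phi (tanh interfaces), returned as a `dpd_profile`.
#' * `synthetic_pmf_samples`: umbrella-window samples drawn exactly from a
#'   known quadratic free-energy surface `U(z) = c z^2` under harmonic
#'   biases (the biased distribution is Gaussian, so sampling is exact);
#'   returns the window list plus the true surface for comparison.
#'
#' @param what One of the fixture names above.
#' @param seed Integer seed; the same seed reproduces the same fixture.
#' @param ... Overrides: `phi` and `n_bins` for `synthetic_profile`;
#'   `c_quad`, `n_windows`, `spacing`, `k`, `n_samples` for
#'   `synthetic_pmf_samples`.
#' @return A `dpd_state`, `dpd_profile`, or window list depending on `what`.
#' @export
#' @examples
#' s <- fixture_generator("bulk64", seed = 7)
fixture_generator <- function(what = c("bulk64", "slab750", "bilayer32",
                                       "synthetic_profile",
                                       "synthetic_pmf_samples"),
                              seed = 1, ...) {
  what <- match.arg(what)
  dots <- list(...)
  switch(what,
    bulk64 = {
      # 64 beads in a sub-cell-list box: exercises the all-pairs path
      side <- (64 / DPD_RHO)^(1 / 3)
      set.seed(seed)
      pos <- matrix(runif(64 * 3, 0, side), 64, 3)
      new_state(pos, mb_velocities(64, 1), rep(1L, 64), "W",
                mol_id = seq_len(64), species = rep("FREE", 64),
                bonds = empty_bonds(), angles = empty_angles(),
                box = rep(side, 3))
    },
    slab750 = build_binary_slab(375, 375, c(5, 5, 10), seed = seed),
    bilayer32 = build_bilayer("DMPC", 32, a_prj = 1.30, Lz = 24, seed = seed),
    synthetic_profile = {
      phi <- if (is.null(dots$phi)) 0.1 else dots$phi
      n_bins <- if (is.null(dots$n_bins)) 80 else dots$n_bins
      Lz <- 20
      zc <- (seq_len(n_bins) - 0.5) * Lz / n_bins
      # A-rich slab in the upper half, tanh interfaces of width 0.5 r0
      fA <- phi + (1 - 2 * phi) *
        (tanh((zc - Lz / 4) / 0.5) - tanh((zc - 3 * Lz / 4) / 0.5)) / 2
      fA <- 1 - fA # A on top
      dens <- rbind(A = 3 * fA, B = 3 * (1 - fA))
      new_profile(zc, dens, "z", Lz / n_bins)
    },
    synthetic_pmf_samples = {
      c_quad <- if (is.null(dots$c_quad)) 2 else dots$c_quad
      n_windows <- if (is.null(dots$n_windows)) 10 else dots$n_windows
      spacing <- if (is.null(dots$spacing)) 0.3 else dots$spacing
      k <- if (is.null(dots$k)) 20 else dots$k
      n_samples <- if (is.null(dots$n_samples)) 4000 else dots$n_samples
      set.seed(seed)
      windows <- lapply(seq_len(n_windows) - 1, function(i) {
        zs <- i * spacing
        # U + bias is quadratic: Gaussian with these moments
        kap <- 2 * c_quad + k
        mu <- k * zs / kap
        sdv <- sqrt(1 / kap)
        list(zstar = zs, k = k, samples = rnorm(n_samples, mu, sdv))
      })
      attr(windows, "true_pmf") <- function(z) c_quad * z^2
      windows
    }
  )
}
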