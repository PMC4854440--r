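# Umbrella sampling for lipid flip-flop and a WHAM solver.
#
# The reaction coordinate is the signed z-offset of the constrained lipid's
# phosphate bead from the instantaneous bilayer mid-plane (mean z of all
# lipid beads), making the profile invariant to membrane drift; an
# absolute-z mode is available by passing ref = NULL to the bias.

#' Generate umbrella windows for a flip-flop profile
#'
#' Window 0 sits at the bilayer centre; window i at `i * spacing` toward and
#' past the equilibrium head-group position. The production force constant
#' is interpreted in kBT/r0^2.
#'
#' @param n Number of windows (>= 2; 61 covers 0 to 9 r0 at the defaults).
#' @param spacing Window spacing in r0.
#' @param k Production force constant in kBT/r0^2.
#' @return A data frame with columns `index`, `zstar`, `k`.
#' @export
#' @examples
#' w <- make_windows()
#' range(w$zstar) # 0 .. 9
make_windows <- function(n = 61, spacing = 0.15, k = 200) {
  stopifnot(n >= 2, spacing > 0, k > 0)
  data.frame(index = seq_len(n) - 1L,
             zstar = (seq_len(n) - 1) * spacing,
             k = k)
}

# phosphate bead (second bead) of a lipid molecule, and the set of all
# lipid beads (the mid-plane reference group)
umbrella_target <- function(state, lipid = NULL) {
  lipid_mols <- which(state$species != "WATER" & state$species != "FREE")
  if (length(lipid_mols) == 0) stop("no lipids in the system")
  if (is.null(lipid)) lipid <- lipid_mols[1]
  rows <- which(state$mol_id == lipid)
  ref <- which(state$species[state$mol_id] != "WATER" &
                 state$species[state$mol_id] != "FREE")
  list(bead = rows[2], ref = ref, lipid = lipid)
}

#' Pull a lipid to an umbrella window
#'
#' Runs a biased simulation with a soft force constant that drags the
#' phosphate bead of the constrained lipid to the window centre, producing
#' the starting structure for that window.
#'
#' @param state An equilibrated bilayer `dpd_state`.
#' @param ff A `dpd_forcefield`.
#' @param window One row of [make_windows()] (list/data frame with `zstar`).
#' @param lipid Molecule id of the constrained lipid (default: first lipid).
#' @param k_pull Soft pulling force constant, kBT/r0^2.
#' @param steps Pulling simulation length.
#' @param dt Time step.
#' @param seed Integer seed.
#' @return List with the pulled `state` and the target description.
#' @export
pull_to_window <- function(state, ff, window, lipid = NULL, k_pull = 10,
                           steps = 10000, dt = 0.02, seed = 1) {
  tgt <- umbrella_target(state, lipid)
  out <- run_dpd(state, ff, steps, dt = dt, seed = seed, sample_stride = 0L,
                 umbrella = list(bead = tgt$bead, k = k_pull,
                                 zstar = window$zstar, ref = tgt$ref))
  list(state = out$state, target = tgt)
}

#' Run one umbrella window
#'
#' Biased NVT dynamics at the full force constant: an equilibration phase
#' followed by a production phase during which the reaction-coordinate
#' samples are collected.
#'
#' @inheritParams pull_to_window
#' @param equil,prod Equilibration and production step counts.
#' @param sample_stride Steps between reaction-coordinate samples.
#' @return List with `samples` (production z-offsets), `window`, `state`.
#' @export
run_window <- function(state, ff, window, lipid = NULL, equil = 50000,
                       prod = 50000, sample_stride = 10, dt = 0.02, seed = 1) {
  tgt <- umbrella_target(state, lipid)
  umb <- list(bead = tgt$bead, k = window$k, zstar = window$zstar,
              ref = tgt$ref)
  eq <- run_dpd(state, ff, equil, dt = dt, seed = seed, sample_stride = 0L,
                umbrella = umb)
  pr <- run_dpd(eq$state, ff, prod, dt = dt, seed = seed,
                sample_stride = sample_stride, umbrella = umb)
  if (detect_rupture(pr$state) == "ruptured") {
    warning("membrane ruptured during umbrella window ", window$index)
  }
  # drop the initial sample (the equilibration end state): prod/stride left
  list(samples = pr$umbrella_samples[-1], window = window, state = pr$state)
}

#' Weighted histogram analysis of umbrella-window samples
#'
#' Standard self-consistent WHAM over binned biased histograms: iterates the
#' unbiased distribution and per-window free energies until the largest
#' change in window free energy falls below `tol`, then reports the
#' potential of mean force shifted so its minimum is zero.
#'
#' @param windows A list, one element per window, each a list with `zstar`,
#'   `k`, and `samples` (reaction-coordinate values).
#' @param bin_width Histogram bin width in r0.
#' @param temperature Reduced temperature.
#' @param tol Convergence tolerance on window free energies (kBT).
#' @param max_iter Iteration cap.
#' @return An object of class `dpd_pmf`: `grid`, `pmf` (kBT, min = 0),
#'   `iterations`, `residual`, `overlap` (adjacent-window histogram overlap
#'   counts), `window_free_energies`.
#' @export
wham <- function(windows, bin_width = 0.05, temperature = 1, tol = 1e-6,
                 max_iter = 50000) {
  stopifnot(length(windows) >= 1)
  zstar <- vapply(windows, function(w) w$zstar, numeric(1))
  kk <- vapply(windows, function(w) w$k, numeric(1))
  all_s <- unlist(lapply(windows, function(w) w$samples))
  lo <- floor(min(all_s) / bin_width) * bin_width
  hi <- ceiling(max(all_s) / bin_width) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (length(edges) < 2) edges <- c(lo, lo + bin_width)
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  nb <- length(mids)
  nw <- length(windows)
  H <- matrix(0, nw, nb)
  N <- numeric(nw)
  for (i in seq_len(nw)) {
    cnt <- tabulate(pmin(pmax(findInterval(windows[[i]]$samples, edges,
                                           rightmost.closed = TRUE), 1), nb),
                    nbins = nb)
    H[i, ] <- cnt
    N[i] <- sum(cnt)
  }
  # adjacent-window overlap diagnostics (windows ordered by zstar)
  ord <- order(zstar)
  overlap <- vapply(seq_len(nw - 1), function(m) {
    sum(H[ord[m], ] > 0 & H[ord[m + 1], ] > 0)
  }, numeric(1))
  if (nw > 1 && any(overlap == 0)) {
    gaps <- which(overlap == 0)
    stop("non-overlapping adjacent windows at zstar = ",
         paste(sprintf("%.3f-%.3f", zstar[ord[gaps]], zstar[ord[gaps + 1]]),
               collapse = ", "))
  }
  beta <- 1 / temperature
  # bias factors c_ib = exp(-beta U_i(x_b))
  C <- exp(-beta * 0.5 * outer(kk, rep(1, nb)) *
             (matrix(mids, nw, nb, byrow = TRUE) - zstar)^2)
  f <- numeric(nw) # window free energies (units kBT, as exp(beta f) weights)
  hsum <- colSums(H)
  resid <- Inf
  iter <- 0
  while (iter < max_iter && resid > tol) {
    iter <- iter + 1
    denom <- colSums(N * exp(beta * f) * C)
    P <- hsum / pmax(denom, .Machine$double.xmin)
    fnew <- -temperature * log(pmax(C %*% P, .Machine$double.xmin))
    fnew <- fnew - fnew[1]
    resid <- max(abs(fnew - f))
    f <- as.numeric(fnew)
  }
  P <- hsum / pmax(colSums(N * exp(beta * f) * C), .Machine$double.xmin)
  ok <- hsum > 0
  pmf <- rep(NA_real_, nb)
  pmf[ok] <- -temperature * log(P[ok])
  pmf <- pmf - min(pmf, na.rm = TRUE)
  structure(list(grid = mids, pmf = pmf, iterations = iter, residual = resid,
                 overlap = overlap, window_free_energies = f),
            class = "dpd_pmf")
}

#' @export
print.dpd_pmf <- function(x, ...) {
  cat(sprintf("PMF on [%.2f, %.2f] r0 (%d bins), WHAM %d iterations (residual %.2g)\n",
              min(x$grid), max(x$grid), length(x$grid), x$iterations, x$residual))
  invisible(x)
}

#' Flip-flop barrier from a PMF
#'
#' The free-energy cost of moving the head group from its equilibrium
#' position (the PMF's global minimum) to the bilayer centre (z = 0).
#'
#' @param pmf A `dpd_pmf`.
#' @param units A [dpd_units()] object.
#' @return List with `barrier` (kBT), `barrier_kJmol`, and `z_min` (r0), the
#'   equilibrium head-group position. Warns when the minimum sits at the
#'   domain edge (insufficient window coverage).
#' @export
pmf_barrier <- function(pmf, units = dpd_units()) {
  ok <- is.finite(pmf$pmf)
  grid <- pmf$grid[ok]; val <- pmf$pmf[ok]
  imin <- which.min(val)
  if (imin == 1 || imin == length(val)) {
    warning("PMF minimum at the domain edge: window coverage may be insufficient")
  }
  icen <- which.min(abs(grid))
  barrier <- val[icen] - val[imin]
  list(barrier = barrier,
       barrier_kJmol = to_physical(barrier, "energy_kJmol", units),
       z_min = grid[imin])
}

#' Full umbrella-sampling flip-flop profile
#'
#' Sequentially pulls the constrained lipid window to window (each pull
#' starting from the previous window's end state), runs each window, and
#' reconstructs the PMF by WHAM. At the defaults this is the production
#' protocol (61 windows x 10^5 steps) and is intended for long-run use;
#' reduced window counts and step numbers give a quick qualitative profile.
#'
#' @param state Equilibrated bilayer `dpd_state`.
#' @param ff A `dpd_forcefield`.
#' @param windows Data frame from [make_windows()].
#' @param lipid Constrained lipid molecule id.
#' @param k_pull,pull_steps Pulling-phase parameters.
#' @param equil,prod,sample_stride Per-window run parameters.
#' @param bin_width WHAM bin width.
#' @param dt Time step.
#' @param seed Integer seed.
#' @return List with the `dpd_pmf`, the per-window sample lists, and the
#'   barrier summary.
#' @export
flipflop_pmf <- function(state, ff, windows = make_windows(), lipid = NULL,
                         k_pull = 10, pull_steps = 10000, equil = 50000,
                         prod = 50000, sample_stride = 10, bin_width = 0.05,
                         dt = 0.02, seed = 1) {
  cur <- state
  results <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    pulled <- pull_to_window(cur, ff, w, lipid = lipid, k_pull = k_pull,
                             steps = pull_steps, dt = dt, seed = seed + i)
    run <- run_window(pulled$state, ff, w, lipid = lipid, equil = equil,
                      prod = prod, sample_stride = sample_stride, dt = dt,
                      seed = seed + 1000 + i)
    results[[i]] <- list(zstar = w$zstar, k = w$k, samples = run$samples)
    cur <- run$state # sequential window generation for continuity
  }
  pmf <- wham(results, bin_width = bin_width, temperature = ff$temperature)
  list(pmf = pmf, windows = results, barrier = pmf_barrier(pmf))
}
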