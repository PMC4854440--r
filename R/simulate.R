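# R-side driver around the compiled DPD engine.

state_amat <- function(state, ff) {
  labs <- state$type_labels
  if (!all(labs %in% rownames(ff$repulsion))) {
    stop("force field does not parameterize bead type(s): ",
         paste(setdiff(labs, rownames(ff$repulsion)), collapse = ", "))
  }
  list(a = ff$repulsion[labs, labs, drop = FALSE],
       g = ff$friction[labs, labs, drop = FALSE])
}

angles_radians <- function(angles) {
  if (nrow(angles) == 0) {
    return(matrix(0, 0, 5))
  }
  cbind(angles$i, angles$j, angles$k, angles$theta0 * pi / 180, angles$K3)
}

bonds_matrix <- function(bonds) {
  if (nrow(bonds) == 0) {
    return(matrix(0, 0, 4))
  }
  cbind(bonds$i, bonds$j, bonds$L0, bonds$K2)
}

#' Advance a DPD system in time
#'
#' Integrates the equations of motion with the Groot-Warren modified
#' velocity-Verlet scheme (prediction parameter 0.5, dissipative force
#' recomputed after the position update). The pairwise random/dissipative
#' forces act as the thermostat; optionally a semi-isotropic Langevin-piston
#' barostat holds the normal pressure at `p_target` while driving the
#' tangential pressure to the same target, which enforces zero surface
#' tension on average.
#'
#' @param state A `dpd_state`.
#' @param ff A `dpd_forcefield`.
#' @param steps Number of time steps.
#' @param dt Time step in tau (default 0.02).
#' @param ensemble `"nvt"` or `"npt"` (constant normal pressure, zero
#'   tension; bilayer normal along z).
#' @param seed Integer seed; together with the state's step counter it fully
#'   determines the noise stream, so runs are reproducible and resumable.
#' @param sample_stride Record temperature/pressure/box every this many
#'   steps (0 disables).
#' @param frame_stride Store position snapshots every this many steps
#'   (0 disables).
#' @param zhist_bins If > 0, accumulate a per-type histogram of z positions
#'   at every sample (cheap time-averaged density profile).
#' @param umbrella Optional harmonic bias: `list(bead =, k =, zstar =,
#'   ref =)` where `ref` is an integer vector of beads whose mean z defines
#'   the reference plane (NULL for absolute z).
#' @param p_target Target pressure for the barostat, kBT/r0^3.
#' @param piston Langevin piston parameters: `list(mass =, gamma =)`;
#'   defaults give overdamped box relaxation within a few thousand steps.
#' @return A list with elements `state` (advanced `dpd_state`), `samples`
#'   (data frame: step, time, temperature, Pxx, Pyy, Pzz, Lx, Ly, Lz),
#'   `zhist` (profile accumulator or NULL), `umbrella_samples` (numeric
#'   vector of reaction-coordinate samples), and `frames` (a `dpd_traj` or
#'   NULL).
#' @export
#' @examples
#' s <- build_bulk(c(5, 5, 5), seed = 1)
#' out <- run_dpd(s, default_forcefield(), steps = 50, seed = 1)
#' mean(out$samples$temperature)
run_dpd <- function(state, ff, steps, dt = 0.02,
                    ensemble = c("nvt", "npt"), seed = 1,
                    sample_stride = 10L, frame_stride = 0L,
                    zhist_bins = 0L, umbrella = NULL,
                    p_target = 89, piston = list(mass = 500, gamma = 1)) {
  ensemble <- match.arg(ensemble)
  mats <- state_amat(state, ff)
  umb <- NULL
  if (!is.null(umbrella)) {
    umb <- list(bead = as.integer(umbrella$bead), k = umbrella$k,
                zstar = umbrella$zstar,
                ref = if (is.null(umbrella$ref)) NULL else as.integer(umbrella$ref))
  }
  opts <- list(ensemble = if (ensemble == "npt") 1L else 0L,
               p_target = p_target,
               piston_mass = piston$mass, piston_gamma = piston$gamma,
               sample_stride = as.integer(sample_stride),
               zhist_bins = as.integer(zhist_bins),
               frame_stride = as.integer(frame_stride),
               umbrella = umb)
  # resuming a run: reuse the stored end-of-run forces so the continuation
  # reproduces the uninterrupted trajectory exactly
  if (!is.null(state$forces) && nrow(state$forces) == nrow(state$pos) &&
      is.null(umbrella)) {
    opts$init_forces <- state$forces
    opts$init_virial <- state$virial
  }
  res <- dpd_run_cpp(state$pos, state$vel, state$type,
                     mats$a, mats$g,
                     bonds_matrix(state$bonds), angles_radians(state$angles),
                     state$box, dt, as.integer(steps), ff$temperature,
                     as.double(seed), as.double(state$step), opts)
  if (isTRUE(res$failed)) stop("DPD run failed: ", res$failmsg)
  out_state <- state
  out_state$pos <- res$pos
  out_state$vel <- res$vel
  out_state$box <- as.numeric(res$box)
  out_state$time <- state$time + steps * dt
  out_state$step <- res$step_end
  if (is.null(umbrella)) {
    out_state$forces <- res$forces
    out_state$virial <- as.numeric(res$virial)
  } else {
    # biased forces are not reusable by an unbiased continuation
    out_state$forces <- NULL
    out_state$virial <- NULL
  }

  samples <- as.data.frame(res$samples)
  names(samples) <- c("step", "time", "temperature",
                      "Pxx", "Pyy", "Pzz", "Lx", "Ly", "Lz")

  zhist <- NULL
  if (zhist_bins > 0) {
    zhist <- list(counts = res$zhist, nsamp = res$zhist_nsamp,
                  box = out_state$box, type_labels = state$type_labels)
  }
  frames <- NULL
  if (frame_stride > 0) {
    frames <- new_traj(out_state, res$frames)
  }
  list(state = out_state, samples = samples, zhist = zhist,
       umbrella_samples = as.numeric(res$umbrella_samples), frames = frames)
}

#' Single-point forces and virial
#'
#' Evaluates the conservative, dissipative, random and bonded forces for a
#' configuration; mostly useful for testing and for computing the pressure
#' tensor of stored frames. The random force is keyed by `(seed, step)`, so
#' repeated calls with the same arguments are identical.
#'
#' @inheritParams run_dpd
#' @param use_cell_list Use the O(N) cell list (TRUE) or the all-pairs
#'   reference path (FALSE); both produce bitwise-identical forces.
#' @param step Step index keying the random-force draw.
#' @return A list with `forces` (N x 3), `virial` (conservative + bonded
#'   diagonal virial, length 3) and `n_pairs`.
#' @export
compute_forces <- function(state, ff, dt = 0.02, seed = 1, step = 0,
                           use_cell_list = TRUE) {
  mats <- state_amat(state, ff)
  compute_forces_cpp(state$pos, state$vel, state$type, mats$a, mats$g,
                     bonds_matrix(state$bonds), angles_radians(state$angles),
                     state$box, dt, ff$temperature,
                     as.double(seed), as.double(step), use_cell_list)
}

#' Instantaneous pressure tensor (diagonal)
#'
#' Kinetic plus virial pressure, the virial taken over conservative pairwise
#' and bonded forces (the dissipative and random contributions average to
#' zero and are excluded, as is standard).
#'
#' @param state A `dpd_state`.
#' @param ff A `dpd_forcefield`.
#' @return Named numeric vector `c(Pxx, Pyy, Pzz)` in kBT/r0^3.
#' @export
pressure_tensor <- function(state, ff) {
  f <- compute_forces(state, ff)
  kin <- colSums(state$vel^2)
  p <- (kin + f$virial) / state_volume(state)
  setNames(as.numeric(p), c("Pxx", "Pyy", "Pzz"))
}

#' Bonded potential energy of a configuration
#'
#' Sum of harmonic bond energies `0.5 K2 (r - L0)^2` and cosine bending
#' energies `K3 [1 - cos(theta - theta0)]`.
#'
#' @param state A `dpd_state`.
#' @return Energy in kBT.
#' @export
bonded_energy <- function(state) {
  bonded_energy_cpp(state$pos, bonds_matrix(state$bonds),
                    angles_radians(state$angles), state$box)
}
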