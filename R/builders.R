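# Initial-configuration builders: bulk fluid, pre-separated binary slab,
# planar bilayer, and free-standing patch for vesicle self-assembly.
# All builders are deterministic given a seed, produce zero total momentum,
# in-box coordinates, and bead counts matching rho * V within rounding.

DPD_RHO <- 3 # reference bead density, beads per r0^3

#' Build a bulk fluid
#'
#' Uniformly random positions at density 3, Maxwell-Boltzmann velocities at
#' the requested temperature, zero total momentum.
#'
#' @param box Numeric length-3 box edge lengths in r0 (each >= 3).
#' @param composition Named integer vector of bead counts per type label
#'   (e.g. `c(W = 3000)`); must sum to `round(3 * prod(box))` within 1.
#' @param temperature Reduced temperature for the velocity draw.
#' @param seed Integer seed.
#' @return A `dpd_state`.
#' @export
#' @examples
#' s <- build_bulk(c(5, 5, 5), c(W = 375), seed = 1)
build_bulk <- function(box, composition = NULL, temperature = 1, seed = 1) {
  box <- as.numeric(box)
  stopifnot(length(box) == 3, all(box >= 3))
  n_target <- round(DPD_RHO * prod(box))
  if (is.null(composition)) composition <- c(W = n_target)
  n <- sum(composition)
  if (abs(n - n_target) > 1) {
    stop(sprintf("composition has %d beads; density 3 requires %d", n, n_target))
  }
  set.seed(seed)
  pos <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
  vel <- mb_velocities(n, temperature)
  labels <- names(composition)
  type <- rep(seq_along(labels), composition)
  new_state(pos, vel, type, labels, mol_id = seq_len(n),
            species = rep("FREE", n), bonds = empty_bonds(),
            angles = empty_angles(), box = box)
}

#' Build a pre-separated binary slab
#'
#' A-type beads uniformly in the upper half of the box (z > Lz/2), B-type in
#' the lower half: the pre-demixed start used to measure the Flory-Huggins
#' chi-parameter of a binary DPD fluid.
#'
#' @param nA,nB Bead counts; `nA + nB` must equal `round(3 * prod(box))`.
#' @param box Length-3 box in r0.
#' @param temperature Reduced temperature.
#' @param seed Integer seed.
#' @return A `dpd_state` with type labels `A`, `B`.
#' @export
#' @examples
#' s <- build_binary_slab(375, 375, c(5, 5, 10), seed = 1)
build_binary_slab <- function(nA, nB, box, temperature = 1, seed = 1) {
  box <- as.numeric(box)
  stopifnot(length(box) == 3, all(box >= 3))
  n_target <- round(DPD_RHO * prod(box))
  if (nA + nB != n_target) {
    stop(sprintf("nA + nB = %d but density 3 requires %d beads", nA + nB, n_target))
  }
  set.seed(seed)
  zA <- runif(nA, box[3] / 2, box[3])
  zB <- runif(nB, 0, box[3] / 2)
  n <- nA + nB
  pos <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), c(zA, zB))
  vel <- mb_velocities(n, temperature)
  type <- c(rep(1L, nA), rep(2L, nB))
  new_state(pos, vel, type, c("A", "B"), mol_id = seq_len(n),
            species = rep("FREE", n), bonds = empty_bonds(),
            angles = empty_angles(), box = box)
}

# z-depth of each bead below the head bead for an extended lipid: follow
# the backbone of tail 1, branch the second glycerol off the short 3-x bond.
lipid_depths <- function(template) {
  n <- length(template$bead_types)
  depth <- rep(NA_real_, n)
  depth[1] <- 0
  # breadth-first over bonds, accumulating L0 along the graph
  b <- template$bonds
  repeat {
    done <- TRUE
    for (r in seq_len(nrow(b))) {
      i <- b$i[r]; j <- b$j[r]
      if (!is.na(depth[i]) && is.na(depth[j])) { depth[j] <- depth[i] + b$L0[r]; done <- FALSE }
      if (!is.na(depth[j]) && is.na(depth[i])) { depth[i] <- depth[j] + b$L0[r]; done <- FALSE }
    }
    if (done) break
  }
  depth
}

# in-plane offset separating the two tails so the initial h-shape is not
# self-overlapping
lipid_xoff <- function(template) {
  chains <- template_chains(template)
  xoff <- rep(0, length(template$bead_types))
  if (length(chains) >= 2) {
    second <- chains[[2]]
    xoff[c(second[1] - 1, second)] <- 0.35 # second glycerol + its tail
  }
  xoff
}

#' Build a planar bilayer with solvent
#'
#' Places `n_lipids` lipids on two opposing leaflet lattices about the box
#' mid-plane (heads outward, tails inward, extended along z with bonds at
#' their rest lengths plus a small in-plane jitter), sets
#' `Lx = Ly = sqrt(n_lipids * a_prj / 2)` from the desired projected area
#' per lipid, and fills the remaining volume with water beads to overall
#' density 3, excluding a slab of half-thickness 3 r0 so no water starts
#' trapped in the membrane core.
#'
#' @param species Lipid species name, see [lipid_template()].
#' @param n_lipids Even number of lipids (half per leaflet).
#' @param a_prj Projected area per lipid in r0^2.
#' @param Lz Box height in r0.
#' @param temperature Reduced temperature.
#' @param jitter In-plane lattice jitter standard deviation in r0.
#' @param seed Integer seed.
#' @return A `dpd_state`.
#' @export
#' @examples
#' s <- build_bilayer("DMPC", 32, a_prj = 1.30, seed = 1)
build_bilayer <- function(species = "DMPC", n_lipids = 1152, a_prj = 1.30,
                          Lz = 24, temperature = 1, jitter = 0.1, seed = 1) {
  stopifnot(n_lipids %% 2 == 0, a_prj > 0, Lz >= 3)
  tpl <- lipid_template(species)
  Lxy <- sqrt(n_lipids * a_prj / 2)
  box <- c(Lxy, Lxy, Lz)
  set.seed(seed)
  per_leaf <- n_lipids / 2
  nx <- ceiling(sqrt(per_leaf))
  spacing <- Lxy / nx
  depth <- lipid_depths(tpl)
  xoff <- lipid_xoff(tpl)
  nb <- length(tpl$bead_types)
  z_mid <- Lz / 2
  head_h <- max(depth) + 0.3 # head stand-off from the mid-plane

  lipid_pos <- matrix(NA_real_, n_lipids * nb, 3)
  idx <- 0
  for (leaf in c(1, -1)) {
    placed <- 0
    for (iy in seq_len(nx)) {
      for (ix in seq_len(nx)) {
        if (placed >= per_leaf) break
        placed <- placed + 1
        cx <- (ix - 0.5) * spacing + rnorm(1, sd = jitter)
        cy <- (iy - 0.5) * spacing + rnorm(1, sd = jitter)
        zs <- z_mid + leaf * (head_h - depth)
        rows <- idx + seq_len(nb)
        lipid_pos[rows, 1] <- cx + xoff
        lipid_pos[rows, 2] <- cy
        lipid_pos[rows, 3] <- zs
        idx <- idx + nb
      }
    }
  }

  n_lipid_beads <- n_lipids * nb
  n_total <- round(DPD_RHO * prod(box))
  n_w <- n_total - n_lipid_beads
  if (n_w < 0) stop("box too small to hold the lipids at density 3")
  # water outside the membrane slab
  slab_half <- 3
  wz <- runif(n_w, 0, Lz - 2 * slab_half)
  wz <- ifelse(wz < z_mid - slab_half, wz, wz + 2 * slab_half)
  w_pos <- cbind(runif(n_w, 0, Lxy), runif(n_w, 0, Lxy), wz)

  topo <- assemble_topology(list(tpl), n_lipids)
  pos <- wrap_positions(rbind(lipid_pos, w_pos), box)
  n <- nrow(pos)
  vel <- mb_velocities(n, temperature)
  type <- c(bead_index(topo$bead_types), rep(bead_index("W"), n_w))
  mol_id <- c(topo$mol_id, max(topo$mol_id) + seq_len(n_w))
  new_state(pos, vel, type, BEAD_LABELS, mol_id,
            species = c(topo$species, rep("WATER", n_w)),
            bonds = topo$bonds, angles = topo$angles, box = box)
}

#' Build a free-standing bilayer patch for vesicle self-assembly
#'
#' A square bilayer patch (built as in [build_bilayer()]) centred in an
#' enlarged water box so the patch edge does not interact with its periodic
#' images; self-assembly then closes the patch into a vesicle.
#'
#' @param species Lipid species.
#' @param n_lipids Even lipid count.
#' @param a_prj Projected area per lipid in r0^2.
#' @param margin Extra box length added to the patch side in every
#'   dimension, in r0.
#' @param temperature Reduced temperature.
#' @param seed Integer seed.
#' @return A `dpd_state`.
#' @export
build_vesicle_start <- function(species = "DMPC", n_lipids = 1152,
                                a_prj = 1.30, margin = 12, temperature = 1,
                                seed = 1) {
  stopifnot(n_lipids %% 2 == 0, margin > 0)
  patch_side <- sqrt(n_lipids * a_prj / 2)
  Lbig <- patch_side + margin
  if (margin < 4) stop("box too small: patch would see its periodic images")
  tpl <- lipid_template(species)
  set.seed(seed)
  # reuse the bilayer layout on the patch footprint, then recentre
  patch <- build_bilayer(species, n_lipids, a_prj, Lz = Lbig,
                         temperature = temperature, seed = seed)
  nb <- length(tpl$bead_types)
  n_lipid_beads <- n_lipids * nb
  lipid_pos <- patch$pos[seq_len(n_lipid_beads), , drop = FALSE]
  shift <- (Lbig - patch_side) / 2
  lipid_pos[, 1] <- lipid_pos[, 1] + shift
  lipid_pos[, 2] <- lipid_pos[, 2] + shift
  box <- c(Lbig, Lbig, Lbig)
  n_total <- round(DPD_RHO * prod(box))
  n_w <- n_total - n_lipid_beads
  z_mid <- Lbig / 2
  # water everywhere except the patch slab footprint
  w_pos <- matrix(NA_real_, 0, 3)
  need <- n_w
  while (need > 0) {
    cand <- cbind(runif(2 * need, 0, Lbig), runif(2 * need, 0, Lbig),
                  runif(2 * need, 0, Lbig))
    inside <- abs(cand[, 3] - z_mid) < 3 &
      cand[, 1] > shift & cand[, 1] < shift + patch_side &
      cand[, 2] > shift & cand[, 2] < shift + patch_side
    cand <- cand[!inside, , drop = FALSE]
    take <- min(nrow(cand), need)
    w_pos <- rbind(w_pos, cand[seq_len(take), , drop = FALSE])
    need <- n_w - nrow(w_pos)
  }
  topo <- assemble_topology(list(tpl), n_lipids)
  pos <- wrap_positions(rbind(lipid_pos, w_pos), box)
  vel <- mb_velocities(nrow(pos), temperature)
  type <- c(bead_index(topo$bead_types), rep(bead_index("W"), n_w))
  mol_id <- c(topo$mol_id, max(topo$mol_id) + seq_len(n_w))
  new_state(pos, vel, type, BEAD_LABELS, mol_id,
            species = c(topo$species, rep("WATER", n_w)),
            bonds = topo$bonds, angles = topo$angles, box = box)
}
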