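# Shared helpers: tiny force fields and hand-built states.

# single-type water force field with the default like-bead repulsion
water_ff <- function(a = 100, gamma = NULL) {
  m <- matrix(a, 1, 1, dimnames = list("W", "W"))
  g <- if (is.null(gamma)) NULL else matrix(gamma, 1, 1, dimnames = list("W", "W"))
  forcefield(m, friction = g)
}

# effectively bonded-only force field (vanishing repulsion and friction)
bonded_only_ff <- function() {
  labs <- c("W", "Q0", "Qa", "Na", "C")
  m <- matrix(1e-300, 5, 5, dimnames = list(labs, labs))
  forcefield(m, friction = m)
}

# a free-bead state from raw positions (no bonds)
free_state <- function(pos, box, vel = NULL, labels = "W",
                       type = rep(1L, nrow(pos))) {
  if (is.null(vel)) vel <- matrix(0, nrow(pos), 3)
  dpdlipid:::new_state(pos, vel, type, labels, mol_id = seq_len(nrow(pos)),
                       species = rep("FREE", nrow(pos)),
                       bonds = dpdlipid:::empty_bonds(),
                       angles = dpdlipid:::empty_angles(), box = box)
}

# a state holding one molecule of the given template at arbitrary positions
molecule_state <- function(template, pos, box, vel = NULL) {
  n <- nrow(pos)
  stopifnot(n == length(template$bead_types))
  if (is.null(vel)) vel <- matrix(0, n, 3)
  dpdlipid:::new_state(pos, vel, dpdlipid:::bead_index(template$bead_types),
                       dpdlipid:::BEAD_LABELS, mol_id = rep(1L, n),
                       species = template$name, bonds = template$bonds,
                       angles = template$angles, box = box)
}

# append free water beads to a state (for rupture-detection fixtures)
append_water <- function(state, wpos) {
  n_old <- nrow(state$pos)
  nw <- nrow(wpos)
  state$pos <- rbind(state$pos, wpos)
  state$vel <- rbind(state$vel, matrix(0, nw, 3))
  state$type <- c(state$type, rep(dpdlipid:::bead_index("W"), nw))
  old_mols <- max(state$mol_id)
  state$mol_id <- c(state$mol_id, old_mols + seq_len(nw))
  state$species <- c(state$species, rep("WATER", nw))
  state
}

# toy two-leaflet system: n_side^2 lipids per leaflet, heads at
# z_mid +- head_z, tails pointing inward; used by structure observables
toy_bilayer_state <- function(head_z = 2.5, n_side = 2, box = c(6, 6, 12)) {
  tpl <- lipid_template("DMPC")
  nb <- length(tpl$bead_types)
  depth <- dpdlipid:::lipid_depths(tpl)
  z_mid <- box[3] / 2
  pos_list <- list()
  for (leaf in c(1, -1)) {
    for (ix in seq_len(n_side)) {
      for (iy in seq_len(n_side)) {
        z <- z_mid + leaf * (head_z - depth * head_z / max(depth))
        pos_list[[length(pos_list) + 1]] <-
          cbind(rep((ix - 0.5) * box[1] / n_side, nb),
                rep((iy - 0.5) * box[2] / n_side, nb), z)
      }
    }
  }
  n_lip <- 2 * n_side^2
  pos <- do.call(rbind, pos_list)
  topo <- dpdlipid:::assemble_topology(list(tpl), n_lip)
  dpdlipid:::new_state(pos, matrix(0, nrow(pos), 3),
                       dpdlipid:::bead_index(topo$bead_types),
                       dpdlipid:::BEAD_LABELS, topo$mol_id, topo$species,
                       topo$bonds, topo$angles, box)
}
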