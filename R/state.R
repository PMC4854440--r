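# SystemState: positions/velocities (N x 3, reduced units), integer bead
# types indexing a label set, molecule membership, global bonded lists, and
# an orthorhombic periodic box.

new_state <- function(pos, vel, type, type_labels, mol_id, species,
                      bonds, angles, box, time = 0, step = 0) {
  structure(
    list(pos = pos, vel = vel, type = as.integer(type),
         type_labels = type_labels, mol_id = as.integer(mol_id),
         species = species, bonds = bonds, angles = angles,
         box = as.numeric(box), time = time, step = step),
    class = "dpd_state"
  )
}

#' @export
print.dpd_state <- function(x, ...) {
  cat(sprintf("DPD system: %d beads (%s) in %.2f x %.2f x %.2f box, t = %g tau\n",
              nrow(x$pos),
              paste(sprintf("%s:%d", x$type_labels,
                            tabulate(x$type, length(x$type_labels))),
                    collapse = " "),
              x$box[1], x$box[2], x$box[3], x$time))
  cat(sprintf("  %d molecules, %d bonds, %d angles\n",
              length(unique(x$mol_id)), nrow(x$bonds), nrow(x$angles)))
  invisible(x)
}

n_beads <- function(state) nrow(state$pos)

state_volume <- function(state) prod(state$box)

# Maxwell-Boltzmann velocities at T with zero total momentum (unit mass)
mb_velocities <- function(n, temperature) {
  v <- matrix(rnorm(3 * n, sd = sqrt(temperature)), n, 3)
  sweep(v, 2, colMeans(v))
}

wrap_positions <- function(pos, box) {
  for (k in 1:3) pos[, k] <- pos[, k] %% box[k]
  pos
}

#' Kinetic temperature of a system
#'
#' Mean kinetic energy per degree of freedom, with three degrees removed for
#' the conserved total momentum.
#'
#' @param state A `dpd_state`.
#' @return Reduced temperature.
#' @export
kinetic_temperature <- function(state) {
  n <- n_beads(state)
  sum(state$vel^2) / (3 * n - 3)
}

#' Total momentum of a system
#'
#' @param state A `dpd_state`.
#' @return Numeric length-3 momentum vector (unit bead mass).
#' @export
total_momentum <- function(state) colSums(state$vel)

# Assemble the global topology for a set of molecules, each an instance of a
# template, given per-molecule first-bead offsets.
assemble_topology <- function(templates, counts) {
  bonds <- list(); angles <- list()
  bead_types <- list(); mol_id <- list(); species <- character(0)
  offset <- 0; mol <- 0
  for (s in seq_along(templates)) {
    tpl <- templates[[s]]
    nb <- length(tpl$bead_types)
    for (m in seq_len(counts[s])) {
      mol <- mol + 1
      bead_types[[length(bead_types) + 1]] <- tpl$bead_types
      mol_id[[length(mol_id) + 1]] <- rep(mol, nb)
      species <- c(species, tpl$name)
      if (nrow(tpl$bonds) > 0) {
        b <- tpl$bonds; b$i <- b$i + offset; b$j <- b$j + offset
        bonds[[length(bonds) + 1]] <- b
      }
      if (nrow(tpl$angles) > 0) {
        a <- tpl$angles; a$i <- a$i + offset; a$j <- a$j + offset; a$k <- a$k + offset
        angles[[length(angles) + 1]] <- a
      }
      offset <- offset + nb
    }
  }
  list(
    bead_types = unlist(bead_types),
    mol_id = unlist(mol_id),
    species = species,
    bonds = if (length(bonds)) do.call(rbind, bonds) else empty_bonds(),
    angles = if (length(angles)) do.call(rbind, angles) else empty_angles()
  )
}
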