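# Structural observables: surface tension, density profiles, membrane
# thickness / area per lipid, chain order, rupture detection.

#' Surface tension of a bilayer-spanning box
#'
#' `gamma_s = < Lz * (Pzz - 0.5 (Pxx + Pyy)) >`, the normal-tangential
#' pressure difference weighted by the box height, averaged over frames or
#' recorded samples. The bilayer normal is assumed along z.
#'
#' @param x Either a samples data frame from [run_dpd()] (columns Pxx, Pyy,
#'   Pzz, Lz) or a `dpd_state`/`dpd_traj` (pressures are then recomputed,
#'   which requires `ff`).
#' @param ff A `dpd_forcefield`, required when `x` holds configurations.
#' @return Surface tension in kBT/r0^2 (with standard error attribute
#'   `"se"` when more than one sample is available).
#' @export
surface_tension <- function(x, ff = NULL) {
  if (is.data.frame(x)) {
    g <- x$Lz * (x$Pzz - 0.5 * (x$Pxx + x$Pyy))
  } else {
    fr <- as_frames(x)
    if (is.null(ff)) stop("ff required to recompute pressures from frames")
    if (length(fr$frames) < 2) {
      warning("fewer than 2 frames: single-frame surface-tension estimate")
    }
    g <- vapply(fr$frames, function(f) {
      s <- frame_state(fr$topology, f)
      p <- pressure_tensor(s, ff)
      s$box[3] * (p["Pzz"] - 0.5 * (p["Pxx"] + p["Pyy"]))
    }, numeric(1))
  }
  out <- mean(g)
  if (length(g) > 1) attr(out, "se") <- sd(g) / sqrt(length(g))
  out
}

#' Per-type number density profile along a box axis
#'
#' @param x A `dpd_state`, `dpd_traj`, or the `zhist` accumulator returned
#'   by [run_dpd()] (a time-averaged histogram collected in the engine).
#' @param axis Axis along which to bin (`"x"`, `"y"` or `"z"`).
#' @param n_bins Number of bins (>= 10); ignored for a `zhist` input.
#' @return An object of class `dpd_profile`: bin `centers` (r0), `density`
#'   matrix (types x bins, beads/r0^3), `fraction` (density normalized to
#'   the local total), type labels, axis and bin width.
#' @export
density_profile <- function(x, axis = "z", n_bins = 40) {
  if (is.list(x) && !is.null(x$counts) && !is.null(x$nsamp)) {
    counts <- x$counts
    L <- x$box
    nb <- ncol(counts)
    bin_w <- L[3] / nb
    vol <- L[1] * L[2] * bin_w
    dens <- counts / (x$nsamp * vol)
    rownames(dens) <- x$type_labels
    return(new_profile((seq_len(nb) - 0.5) * bin_w, dens, "z", bin_w))
  }
  stopifnot(n_bins >= 10)
  ax <- match(axis, c("x", "y", "z"))
  fr <- as_frames(x)
  topo <- fr$topology
  L <- topo$box
  bin_w <- L[ax] / n_bins
  perp <- prod(L[-ax])
  labs <- topo$type_labels
  counts <- matrix(0, length(labs), n_bins, dimnames = list(labs, NULL))
  for (f in fr$frames) {
    b <- pmin(pmax(floor(f[, ax] / bin_w), 0), n_bins - 1) + 1
    for (t in seq_along(labs)) {
      sel <- topo$type == t
      if (any(sel)) counts[t, ] <- counts[t, ] + tabulate(b[sel], n_bins)
    }
  }
  dens <- counts / (length(fr$frames) * perp * bin_w)
  new_profile((seq_len(n_bins) - 0.5) * bin_w, dens, axis, bin_w)
}

new_profile <- function(centers, density, axis, bin_width) {
  total <- colSums(density)
  frac <- sweep(density, 2, pmax(total, .Machine$double.eps), "/")
  structure(list(centers = centers, density = density, fraction = frac,
                 total = total, axis = axis, bin_width = bin_width),
            class = "dpd_profile")
}

#' @export
print.dpd_profile <- function(x, ...) {
  cat(sprintf("Density profile along %s: %d bins of %.3f r0, types: %s\n",
              x$axis, length(x$centers), x$bin_width,
              paste(rownames(x$density), collapse = " ")))
  invisible(x)
}

# z of the bilayer mid-plane: centre of mass of all lipid (non-water) beads
bilayer_midplane <- function(state) {
  lipid <- state$species[state$mol_id] != "WATER" & state$type_labels[state$type] != "W"
  mean(state$pos[lipid, 3])
}

# per-lipid leaflet assignment: a lipid is in the upper leaflet when its
# head (first bead) sits above the midpoint of its own tail beads
leaflet_of <- function(state) {
  lipid_mols <- which(state$species != "WATER" & state$species != "FREE")
  vapply(lipid_mols, function(m) {
    rows <- which(state$mol_id == m)
    head_z <- state$pos[rows[1], 3]
    tail_rows <- rows[state$type_labels[state$type[rows]] == "C"]
    tz <- mean(state$pos[tail_rows, 3])
    if (head_z >= tz) 1L else -1L
  }, integer(1))
}

#' Membrane thickness and area per lipid
#'
#' Thickness is the distance between the mean choline (first head bead, Q0)
#' z-positions of the two leaflets, leaflets assigned by which side of its
#' own tail midpoint each head lies; area per lipid is the projected box
#' area divided by the lipids per leaflet. Averaged over frames.
#'
#' @param x A `dpd_state` or `dpd_traj` holding an intact bilayer.
#' @param units A [dpd_units()] object for the physical twin values.
#' @return List with `l_mem` and `a0` in r0-based units and `l_mem_nm`,
#'   `a0_nm2` in physical units.
#' @export
membrane_structure <- function(x, units = dpd_units()) {
  fr <- as_frames(x)
  topo <- fr$topology
  lipid_mols <- which(topo$species != "WATER" & topo$species != "FREE")
  n_lipids <- length(lipid_mols)
  if (n_lipids < 2) stop("no bilayer present")
  vals <- vapply(fr$frames, function(f) {
    s <- frame_state(topo, f)
    leaf <- leaflet_of(s)
    if (all(leaf == leaf[1])) stop("leaflet assignment ambiguous (single leaflet?)")
    chol <- vapply(lipid_mols, function(m) {
      rows <- which(s$mol_id == m)
      s$pos[rows[1], 3]
    }, numeric(1))
    lm <- abs(mean(chol[leaf == 1]) - mean(chol[leaf == -1]))
    a0 <- s$box[1] * s$box[2] / (n_lipids / 2)
    c(lm, a0)
  }, numeric(2))
  l_mem <- mean(vals[1, ]); a0 <- mean(vals[2, ])
  list(l_mem = l_mem, a0 = a0,
       l_mem_nm = to_physical(l_mem, "length", units),
       a0_nm2 = to_physical(a0, "area", units))
}

#' Hydrocarbon chain orientation order parameter
#'
#' `S_chain = 0.5 <3 cos^2(theta) - 1>` where theta is the angle between the
#' first-to-terminal tail-bead vector of each hydrocarbon chain and the
#' bilayer normal (z). S = 1 for chains along the normal, -0.5 in-plane,
#' 0 for isotropic orientations; ~0.45-0.55 marks a fluid bilayer, ~0.9 gel.
#'
#' @param x A `dpd_state` or `dpd_traj` containing lipids.
#' @param method `"end_to_end"` (default: one vector per chain from first to
#'   terminal tail bead) or `"per_bond"` (average over successive tail-bead
#'   bonds, which weighs local kinks more heavily and gives systematically
#'   lower values).
#' @return The ensemble- and chain-averaged order parameter.
#' @export
chain_order <- function(x, method = c("end_to_end", "per_bond")) {
  method <- match.arg(method)
  fr <- as_frames(x)
  topo <- fr$topology
  lipid_mols <- which(topo$species != "WATER" & topo$species != "FREE")
  if (length(lipid_mols) == 0) stop("no lipids present")
  # chain bead offsets within each species template
  first_rows <- vapply(lipid_mols, function(m) which(topo$mol_id == m)[1], integer(1))
  chains_by_species <- lapply(unique(topo$species[lipid_mols]), function(sp) {
    template_chains(lipid_template(sp))
  })
  names(chains_by_species) <- unique(topo$species[lipid_mols])
  vals <- vapply(fr$frames, function(f) {
    L <- attr(f, "box")
    if (is.null(L)) L <- topo$box
    cos2 <- c()
    for (idx in seq_along(lipid_mols)) {
      sp <- topo$species[lipid_mols[idx]]
      for (ch in chains_by_species[[sp]]) {
        segs <- if (method == "end_to_end") {
          list(c(ch[1], ch[length(ch)]))
        } else {
          lapply(seq_len(length(ch) - 1), function(q) ch[q:(q + 1)])
        }
        for (sg in segs) {
          r1 <- first_rows[idx] + sg[1] - 1
          r2 <- first_rows[idx] + sg[2] - 1
          d <- f[r2, ] - f[r1, ]
          d <- d - L * round(d / L)
          cos2 <- c(cos2, (d[3] / sqrt(sum(d^2)))^2)
        }
      }
    }
    mean(0.5 * (3 * cos2 - 1))
  }, numeric(1))
  mean(vals)
}

#' Classify bilayer integrity by trans-membrane water connectivity
#'
#' A frame contains a pore when a connected chain of water beads (neighbour
#' distance < 1 r0, periodic in-plane) links the region above the bilayer
#' mid-plane (z > mid + margin) to the region below (z < mid - margin).
#' A system is `"intact"` if no frame percolates, `"pore"` if some do, and
#' `"ruptured"` when the pore is sustained (more than 80% of frames) or no
#' bilayer is present at all.
#'
#' @param x A `dpd_state` or `dpd_traj`.
#' @param margin Half-width of the mid-plane band in r0.
#' @return Character scalar: `"intact"`, `"pore"` or `"ruptured"`.
#' @export
detect_rupture <- function(x, margin = 2) {
  fr <- as_frames(x)
  topo <- fr$topology
  if (!any(topo$species != "WATER" & topo$species != "FREE")) {
    return("ruptured") # degenerate: no membrane at all
  }
  percolates <- vapply(fr$frames, function(f) {
    s <- frame_state(topo, f)
    frame_percolates(s, margin)
  }, logical(1))
  if (!any(percolates)) return("intact")
  if (mean(percolates) > 0.8) return("ruptured")
  "pore"
}

frame_percolates <- function(state, margin = 2) {
  zmid <- bilayer_midplane(state)
  is_w <- state$type_labels[state$type] == "W"
  dz <- state$pos[, 3] - zmid
  dz <- dz - state$box[3] * round(dz / state$box[3])
  sel <- which(is_w & abs(dz) < margin + 0.5)
  if (length(sel) == 0) return(FALSE)
  p <- state$pos[sel, , drop = FALSE]
  n <- nrow(p)
  # union-find over water beads within distance 1 (periodic in x, y)
  parent <- seq_len(n)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1)) {
    d <- sweep(p[(i + 1):n, , drop = FALSE], 2, p[i, ])
    for (k in 1:2) d[, k] <- d[, k] - state$box[k] * round(d[, k] / state$box[k])
    hit <- which(rowSums(d^2) < 1)
    for (j in hit + i) {
      ri <- findp(i); rj <- findp(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), findp, integer(1))
  up <- dz[sel] > margin - 0.5
  dn <- dz[sel] < -(margin - 0.5)
  any(roots[up] %in% roots[dn])
}
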