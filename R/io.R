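# Plain-text serialization: extended-XYZ trajectories, a topology sidecar,
# and full-precision versioned checkpoints. All formats round-trip exactly.

fmt_g <- function(x) sprintf("%.17g", x)

#' Write frames as extended XYZ
#'
#' One block per frame: bead count, a comment line carrying the box
#' (`Lattice=...`), properties and time, then one line per bead with the
#' type label, position, and (optionally) velocity at full precision.
#'
#' @param x A `dpd_traj`, `dpd_state`, or list of states.
#' @param path Output file.
#' @param velocities Include velocities (only available for state input).
#' @return `path`, invisibly.
#' @export
write_frames <- function(x, path, velocities = FALSE) {
  fr <- as_frames(x)
  topo <- fr$topology
  labels <- topo$type_labels[topo$type]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in fr$frames) {
    L <- attr(f, "box"); if (is.null(L)) L <- topo$box
    tm <- attr(f, "time"); if (is.null(tm)) tm <- topo$time
    props <- if (velocities) "species:S:1:pos:R:3:vel:R:3" else "species:S:1:pos:R:3"
    writeLines(as.character(nrow(f)), con)
    writeLines(sprintf('Lattice="%s 0 0 0 %s 0 0 0 %s" Properties=%s Time=%s',
                       fmt_g(L[1]), fmt_g(L[2]), fmt_g(L[3]), props, fmt_g(tm)), con)
    if (velocities && inherits(x, "dpd_state")) {
      lines <- paste(labels, fmt_g(f[, 1]), fmt_g(f[, 2]), fmt_g(f[, 3]),
                     fmt_g(x$vel[, 1]), fmt_g(x$vel[, 2]), fmt_g(x$vel[, 3]))
    } else {
      lines <- paste(labels, fmt_g(f[, 1]), fmt_g(f[, 2]), fmt_g(f[, 3]))
    }
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read extended-XYZ frames
#'
#' @param path File written by [write_frames()].
#' @param topology Optional `dpd_state` supplying bonds/angles/molecules;
#'   without it a free-bead topology is reconstructed from the labels.
#' @return A `dpd_traj`.
#' @export
read_frames <- function(path, topology = NULL) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  first_labels <- NULL
  first_vel <- NULL
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop("malformed frame header at line ", i)
    header <- lines[i + 1]
    lat <- regmatches(header, regexpr('Lattice="[^"]*"', header))
    if (length(lat) == 0) stop("missing Lattice in frame header at line ", i + 1)
    nums <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", lat), "\\s+")[[1]])
    L <- nums[c(1, 5, 9)]
    tm <- regmatches(header, regexpr("Time=[-0-9.eE+]+", header))
    tm <- if (length(tm)) as.numeric(sub("Time=", "", tm)) else 0
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(parts, length, 1L) < 4)
    if (length(bad)) stop("malformed bead line at line ", i + 1 + bad[1])
    labs <- vapply(parts, `[[`, "", 1)
    pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(first_labels)) {
      first_labels <- labs
      if (length(parts[[1]]) >= 7) {
        first_vel <- t(vapply(parts, function(p) as.numeric(p[5:7]), numeric(3)))
      }
    }
    attr(pos, "box") <- L
    attr(pos, "time") <- tm
    frames[[length(frames) + 1]] <- pos
    i <- i + 2 + n
  }
  if (is.null(topology)) {
    type_labels <- unique(first_labels)
    n <- length(first_labels)
    topology <- new_state(frames[[1]],
                          if (is.null(first_vel)) matrix(0, n, 3) else first_vel,
                          match(first_labels, type_labels), type_labels,
                          mol_id = seq_len(n), species = rep("FREE", n),
                          bonds = empty_bonds(), angles = empty_angles(),
                          box = attr(frames[[1]], "box"),
                          time = attr(frames[[1]], "time"))
  }
  new_traj(topology, frames)
}

#' Write or read the topology sidecar
#'
#' Bead types, molecule membership, species, bonds and angles as a tagged
#' plain-text file accompanying a trajectory.
#'
#' @param state A `dpd_state`.
#' @param path File path.
#' @return `read_topology` returns a list with the topology fields.
#' @export
write_topology <- function(state, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# dpdlipid topology v1", con)
  writeLines(paste("type_labels", paste(state$type_labels, collapse = " ")), con)
  writeLines(paste("n_beads", nrow(state$pos)), con)
  writeLines(paste("type", paste(state$type, collapse = " ")), con)
  writeLines(paste("mol_id", paste(state$mol_id, collapse = " ")), con)
  writeLines(paste("species",
                   paste(state$species[state$mol_id], collapse = " ")), con)
  writeLines(paste("n_bonds", nrow(state$bonds)), con)
  if (nrow(state$bonds)) {
    writeLines(paste(state$bonds$i, state$bonds$j, fmt_g(state$bonds$L0),
                     fmt_g(state$bonds$K2)), con)
  }
  writeLines(paste("n_angles", nrow(state$angles)), con)
  if (nrow(state$angles)) {
    writeLines(paste(state$angles$i, state$angles$j, state$angles$k,
                     fmt_g(state$angles$theta0), fmt_g(state$angles$K3)), con)
  }
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  lines <- readLines(path)
  stopifnot(grepl("dpdlipid topology", lines[1]))
  sp <- function(l) strsplit(trimws(l), "\\s+")[[1]]
  i <- 2
  out <- list()
  get_kv <- function() { v <- sp(lines[i]); i <<- i + 1; v }
  v <- get_kv(); out$type_labels <- v[-1]
  v <- get_kv(); n <- as.integer(v[2])
  v <- get_kv(); out$type <- as.integer(v[-1])
  v <- get_kv(); out$mol_id <- as.integer(v[-1])
  v <- get_kv(); out$species_per_bead <- v[-1]
  v <- get_kv(); nb <- as.integer(v[2])
  bonds <- empty_bonds()
  if (nb > 0) {
    m <- do.call(rbind, lapply(lines[i:(i + nb - 1)], function(l) as.numeric(sp(l))))
    i <- i + nb
    bonds <- data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
                        L0 = m[, 3], K2 = m[, 4])
  }
  v <- get_kv(); na <- as.integer(v[2])
  angles <- empty_angles()
  if (na > 0) {
    m <- do.call(rbind, lapply(lines[i:(i + na - 1)], function(l) as.numeric(sp(l))))
    angles <- data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
                         k = as.integer(m[, 3]), theta0 = m[, 4], K3 = m[, 5])
  }
  # species per molecule
  mols <- unique(out$mol_id)
  out$species <- out$species_per_bead[match(mols, out$mol_id)]
  out$n_beads <- n
  out$bonds <- bonds
  out$angles <- angles
  out
}

#' Checkpoint a full system state
#'
#' Versioned full-precision plain-text snapshot of positions, velocities,
#' box, topology, time and step counter; `read_checkpoint` restores a state
#' that continues a run exactly (the noise stream is keyed by seed and step
#' counter, not by hidden RNG state).
#'
#' @param state A `dpd_state`.
#' @param path File path.
#' @return `read_checkpoint` returns the restored `dpd_state`.
#' @export
write_checkpoint <- function(state, path) {
  con <- file(path, "w")
  on.exit(close(con))
  has_f <- !is.null(state$forces)
  writeLines("# dpdlipid checkpoint v1", con)
  writeLines(paste("box", paste(fmt_g(state$box), collapse = " ")), con)
  writeLines(paste("time", fmt_g(state$time)), con)
  writeLines(paste("step", fmt_g(state$step)), con)
  writeLines(paste("has_forces", as.integer(has_f)), con)
  if (has_f) {
    writeLines(paste("virial", paste(fmt_g(state$virial), collapse = " ")), con)
  }
  close(con)
  on.exit(NULL)
  write_topology(state, paste0(path, ".top"))
  con <- file(path, "a")
  on.exit(close(con))
  cols <- cbind(state$pos, state$vel, if (has_f) state$forces)
  writeLines(do.call(paste, lapply(seq_len(ncol(cols)),
                                   function(k) fmt_g(cols[, k]))), con)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  lines <- readLines(path)
  stopifnot(grepl("dpdlipid checkpoint", lines[1]))
  sp <- function(l) strsplit(trimws(l), "\\s+")[[1]]
  box <- as.numeric(sp(lines[2])[-1])
  tm <- as.numeric(sp(lines[3])[2])
  step <- as.numeric(sp(lines[4])[2])
  has_f <- as.integer(sp(lines[5])[2]) == 1L
  nhdr <- 5
  virial <- NULL
  if (has_f) {
    virial <- as.numeric(sp(lines[6])[-1])
    nhdr <- 6
  }
  topo <- read_topology(paste0(path, ".top"))
  m <- do.call(rbind, lapply(lines[-seq_len(nhdr)],
                             function(l) as.numeric(sp(l))))
  st <- new_state(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE], topo$type,
                  topo$type_labels, topo$mol_id, topo$species, topo$bonds,
                  topo$angles, box, time = tm, step = step)
  if (has_f) {
    st$forces <- m[, 7:9, drop = FALSE]
    st$virial <- virial
  }
  st
}
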