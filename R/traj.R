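# Trajectory container: a topology (a dpd_state whose positions are only a
# template) plus a list of frames, each a positions matrix with box and time
# attributes.

new_traj <- function(topology, frames) {
  structure(list(topology = topology, frames = frames), class = "dpd_traj")
}

#' @export
print.dpd_traj <- function(x, ...) {
  cat(sprintf("DPD trajectory: %d frames of %d beads\n",
              length(x$frames), nrow(x$topology$pos)))
  invisible(x)
}

#' @export
length.dpd_traj <- function(x) length(x$frames)

# Coerce a state, a traj, or a list of states into a list of (pos, box, time)
# frames plus topology; used by the analysis operations.
as_frames <- function(x) {
  if (inherits(x, "dpd_traj")) {
    return(list(topology = x$topology, frames = x$frames))
  }
  if (inherits(x, "dpd_state")) {
    f <- x$pos
    attr(f, "box") <- x$box
    attr(f, "time") <- x$time
    return(list(topology = x, frames = list(f)))
  }
  if (is.list(x) && all(vapply(x, inherits, TRUE, "dpd_state"))) {
    frames <- lapply(x, function(s) {
      f <- s$pos
      attr(f, "box") <- s$box
      attr(f, "time") <- s$time
      f
    })
    return(list(topology = x[[1]], frames = frames))
  }
  stop("expected a dpd_state, dpd_traj, or list of dpd_state")
}

frame_state <- function(topology, frame) {
  s <- topology
  s$pos <- frame[, , drop = FALSE]
  b <- attr(frame, "box")
  if (!is.null(b)) s$box <- as.numeric(b)
  tm <- attr(frame, "time")
  if (!is.null(tm)) s$time <- tm
  s
}
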