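# Nonbonded force field: symmetric repulsion and friction tables over the
# five bead types, in reduced units.

#' Friction coefficient tier for a given repulsion strength
#'
#' DPD friction coefficients are assigned in three tiers by repulsion
#' strength: 4.5 for low, 9 for intermediate, and 20 for high repulsion.
#' The tier boundaries (`a <= 102`, `102 < a <= 110`, `a > 110`) are chosen
#' so that every distinct repulsion value in the default table falls in
#' exactly one tier; they can be overridden by supplying custom boundaries.
#'
#' @param a Repulsion strength(s), in kBT/r0; must be positive.
#' @param boundaries Two increasing cut points splitting low/mid/high tiers.
#' @param tiers The three friction values, in reduced friction units.
#' @return Friction coefficient(s), same length as `a`.
#' @export
#' @examples
#' friction_for(c(100, 110, 130)) # 4.5, 9, 20
friction_for <- function(a, boundaries = c(102, 110), tiers = c(4.5, 9, 20)) {
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("repulsion strength must be positive and finite")
  }
  stopifnot(length(boundaries) == 2, diff(boundaries) > 0, length(tiers) == 3)
  ifelse(a <= boundaries[1], tiers[1],
         ifelse(a <= boundaries[2], tiers[2], tiers[3]))
}

#' Default nonbonded force field for the four-to-one mapping
#'
#' Returns the symmetric 5x5 repulsion matrix over bead types W, Q0, Qa, Na,
#' C at mapping number Nm = 4 (like-bead repulsion 100, which reproduces the
#' water compressibility of ~16 at room temperature), together with the
#' friction matrix obtained by applying [friction_for()] entrywise and the
#' reduced temperature.
#'
#' Head-group/water attraction is mimicked by sub-water repulsion (98);
#' like-charge head beads repel more strongly (110) in lieu of explicit
#' electrostatics; water/tail repulsion (130) encodes the hydrocarbon-water
#' Flory-Huggins chi of about 8.
#'
#' @param temperature Reduced temperature T* (1 corresponds to 25 C).
#' @param units A [dpd_units()] object.
#' @return An object of class `dpd_forcefield` with elements `repulsion`,
#'   `friction`, `temperature`, `units`.
#' @export
#' @examples
#' ff <- default_forcefield()
#' ff$repulsion["W", "C"] # 130
default_forcefield <- function(temperature = 1, units = dpd_units()) {
  a <- matrix(c(
    100,  98,  98, 102, 130,
     98, 110, 100, 102, 130,
     98, 100, 110, 102, 130,
    102, 102, 102, 100, 110,
    130, 130, 130, 110, 100
  ), nrow = 5, byrow = TRUE, dimnames = list(BEAD_LABELS, BEAD_LABELS))
  forcefield(a, temperature = temperature, units = units)
}

#' Construct a force field from a repulsion matrix
#'
#' @param repulsion Symmetric positive matrix of repulsion strengths with
#'   row/column names naming the bead types.
#' @param friction Optional friction matrix; defaults to [friction_for()]
#'   applied entrywise.
#' @param temperature Reduced temperature.
#' @param units A [dpd_units()] object.
#' @return A `dpd_forcefield` object.
#' @export
forcefield <- function(repulsion, friction = NULL, temperature = 1,
                       units = dpd_units()) {
  repulsion <- as.matrix(repulsion)
  if (!isTRUE(all.equal(repulsion, t(repulsion)))) {
    stop("repulsion matrix must be symmetric")
  }
  if (any(repulsion <= 0)) stop("repulsion entries must be positive")
  if (is.null(friction)) {
    friction <- matrix(friction_for(repulsion), nrow = nrow(repulsion),
                       dimnames = dimnames(repulsion))
  }
  if (!isTRUE(all.equal(friction, t(friction))) || any(friction <= 0)) {
    stop("friction matrix must be symmetric with positive entries")
  }
  structure(
    list(repulsion = repulsion, friction = friction,
         temperature = temperature, units = units),
    class = "dpd_forcefield"
  )
}

#' @export
print.dpd_forcefield <- function(x, ...) {
  cat(sprintf("DPD force field (%d bead types, T* = %g)\nRepulsion a_ij [kBT/r0]:\n",
              nrow(x$repulsion), x$temperature))
  print(x$repulsion)
  cat("Friction gamma_ij:\n")
  print(x$friction)
  invisible(x)
}

# Force field for ad-hoc generic bead mixtures (e.g. the A/B demixing
# experiment): like-bead repulsion a_ii, unlike a_ii + delta.
binary_forcefield <- function(a_ii, delta_a, temperature = 1,
                              units = dpd_units()) {
  a <- matrix(c(a_ii, a_ii + delta_a, a_ii + delta_a, a_ii), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  forcefield(a, temperature = temperature, units = units)
}

#' Write or read a force field as a structured text config
#'
#' @param ff A `dpd_forcefield` object.
#' @param path File path.
#' @return `read_forcefield` returns a `dpd_forcefield`; `write_forcefield`
#'   returns `path` invisibly.
#' @export
write_forcefield <- function(ff, path) {
  obj <- list(
    bead_types = as.list(rownames(ff$repulsion)),
    repulsion = lapply(seq_len(nrow(ff$repulsion)),
                       function(i) as.numeric(ff$repulsion[i, ])),
    friction = lapply(seq_len(nrow(ff$friction)),
                      function(i) as.numeric(ff$friction[i, ])),
    temperature = ff$temperature,
    units = unclass(ff$units)
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_forcefield
#' @export
read_forcefield <- function(path) {
  obj <- yaml::read_yaml(path)
  labs <- unlist(obj$bead_types)
  n <- length(labs)
  rep_m <- matrix(unlist(obj$repulsion), n, n, byrow = TRUE,
                  dimnames = list(labs, labs))
  fr_m <- matrix(unlist(obj$friction), n, n, byrow = TRUE,
                 dimnames = list(labs, labs))
  u <- obj$units
  forcefield(rep_m, fr_m, temperature = obj$temperature,
             units = dpd_units(u$r0_nm, u$tau_ps, u$Nm))
}
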