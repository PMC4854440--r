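# h-shape lipid molecule templates. Bead numbering follows the bonded table:
# 1 = choline (Q0), 2 = phosphate (Qa), 3 = glycerol (Na) carrying tail 1,
# then the first tail's C beads, then the second glycerol (Na, bonded to
# bead 3 by the short 0.31 r0 bond that makes the "h") carrying tail 2.

#' Lipid molecule template
#'
#' Returns the coarse-grained template for a lipid species or the
#' single-bead water "molecule". DMPC has 10 beads (three C beads per tail);
#' DPPC extends each tail by one C bead (two extra CH2 groups per tail);
#' DOPC has DPPC's bead count but the angle ending at each terminal tail
#' bead is bent to 120 degrees to mimic the unsaturated chains. Tail bond
#' lengths are 0.59 r0 with K2 = 512 kBT/r0^2 and tail angles are straight
#' (180 degrees, K3 = 6 kBT) unless noted.
#'
#' @param name One of `"DMPC"`, `"DPPC"`, `"DOPC"`, `"WATER"`.
#' @return An object of class `dpd_template` with fields `name`,
#'   `bead_types` (character vector), `bonds` (data frame i, j, L0, K2) and
#'   `angles` (data frame i, j, k, theta0 in degrees, K3).
#' @export
#' @examples
#' t <- lipid_template("DMPC")
#' nrow(t$bonds)  # 9
#' nrow(t$angles) # 6
lipid_template <- function(name = c("DMPC", "DPPC", "DOPC", "WATER")) {
  name <- match.arg(name)
  if (name == "WATER") {
    return(new_template("WATER", "W",
                        bonds = empty_bonds(), angles = empty_angles()))
  }
  if (name == "DMPC") {
    beads <- c("Q0", "Qa", "Na", "C", "C", "C", "Na", "C", "C", "C")
    bonds <- data.frame(
      i = c(1, 2, 3, 3, 4, 5, 7, 8, 9),
      j = c(2, 3, 7, 4, 5, 6, 8, 9, 10),
      L0 = c(0.47, 0.47, 0.31, 0.59, 0.59, 0.59, 0.59, 0.59, 0.59),
      K2 = rep(512, 9)
    )
    angles <- data.frame(
      i = c(2, 2, 3, 4, 7, 8),
      j = c(3, 3, 4, 5, 8, 9),
      k = c(4, 7, 5, 6, 9, 10),
      theta0 = c(180, 120, 180, 180, 180, 180),
      K3 = rep(6, 6)
    )
    return(new_template(name, beads, bonds, angles))
  }
  # DPPC / DOPC: four C beads per tail; head geometry copies DMPC.
  # Beads: 1 Q0, 2 Qa, 3 Na, 4:7 tail 1, 8 Na, 9:12 tail 2.
  beads <- c("Q0", "Qa", "Na", "C", "C", "C", "C", "Na", "C", "C", "C", "C")
  bonds <- data.frame(
    i = c(1, 2, 3, 3, 4, 5, 6, 8, 9, 10, 11),
    j = c(2, 3, 8, 4, 5, 6, 7, 9, 10, 11, 12),
    L0 = c(0.47, 0.47, 0.31, rep(0.59, 8)),
    K2 = rep(512, 11)
  )
  term_theta <- if (name == "DOPC") 120 else 180
  angles <- data.frame(
    i = c(2, 2, 3, 4, 5, 8, 9, 10),
    j = c(3, 3, 4, 5, 6, 9, 10, 11),
    k = c(4, 8, 5, 6, 7, 10, 11, 12),
    theta0 = c(180, 120, 180, 180, term_theta, 180, 180, term_theta),
    K3 = rep(6, 8)
  )
  new_template(name, beads, bonds, angles)
}

empty_bonds <- function() {
  data.frame(i = integer(), j = integer(), L0 = numeric(), K2 = numeric())
}
empty_angles <- function() {
  data.frame(i = integer(), j = integer(), k = integer(),
             theta0 = numeric(), K3 = numeric())
}

new_template <- function(name, bead_types, bonds, angles) {
  n <- length(bead_types)
  stopifnot(all(c(bonds$i, bonds$j, angles$i, angles$j, angles$k) >= 1),
            all(c(bonds$i, bonds$j, angles$i, angles$j, angles$k) <= n))
  key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
  if (anyDuplicated(key)) stop("duplicate bonds in template")
  bead_index(bead_types) # validates labels (A/B generic handled elsewhere)
  structure(list(name = name, bead_types = bead_types,
                 bonds = bonds, angles = angles),
            class = "dpd_template")
}

#' @export
print.dpd_template <- function(x, ...) {
  cat(sprintf("%s template: %d beads [%s], %d bonds, %d angles\n",
              x$name, length(x$bead_types), paste(x$bead_types, collapse = " "),
              nrow(x$bonds), nrow(x$angles)))
  invisible(x)
}

# Hydrocarbon chains of a template: list of integer vectors of consecutive
# C beads (used by chain-order and builder placement).
template_chains <- function(template) {
  is_c <- template$bead_types == "C"
  r <- rle(is_c)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  lapply(which(r$values), function(k) starts[k]:ends[k])
}
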