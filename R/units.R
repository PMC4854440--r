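# Reduced-unit bookkeeping. Internally everything is in DPD reduced units
# (r0 = m0 = kBT = 1); conversion to physical units happens only at I/O
# boundaries.

# Boltzmann constant times 298.15 K, in joules
KBT_298_J <- 1.380649e-23 * 298.15

#' Reduced-unit system of the four-to-one coarse-grained mapping
#'
#' One bead represents about four heavy atoms, so a water bead carries
#' `Nm = 4` water molecules; matching the bead volume and mass to four waters
#' fixes the length unit at `r0 = 0.71` nm and the time unit at
#' `tau = 143` ps. Thermal energy `kBT` is unity in reduced units and is
#' referenced to 298 K for physical conversions.
#'
#' @param r0_nm Length of one reduced length unit, in nm.
#' @param tau_ps Length of one reduced time unit, in ps.
#' @param Nm Number of water molecules per bead (integer, >= 1).
#' @return An object of class `dpd_units`.
#' @export
#' @examples
#' u <- dpd_units()
#' to_physical(1.30, "area", u) # area per lipid in nm^2
dpd_units <- function(r0_nm = 0.71, tau_ps = 143, Nm = 4L) {
  stopifnot(r0_nm > 0, tau_ps > 0, Nm >= 1)
  structure(
    list(r0_nm = r0_nm, tau_ps = tau_ps, kBT_ref = 1, Nm = as.integer(Nm)),
    class = "dpd_units"
  )
}

#' @export
print.dpd_units <- function(x, ...) {
  cat(sprintf("DPD reduced units: r0 = %g nm, tau = %g ps, Nm = %d (kBT = 1 at 298 K)\n",
              x$r0_nm, x$tau_ps, x$Nm))
  invisible(x)
}

unit_factor <- function(kind, units) {
  # multiplicative factor reduced -> physical
  switch(kind,
    length = units$r0_nm,                       # nm
    area = units$r0_nm^2,                       # nm^2
    time = units$tau_ps,                        # ps
    energy = KBT_298_J,                         # J
    energy_kJmol = KBT_298_J * 6.02214076e23 / 1000, # kJ/mol
    tension = KBT_298_J / (units$r0_nm * 1e-9)^2 * 1e3, # mN/m
    stop("unknown unit kind: ", kind)
  )
}

#' Convert between reduced and physical units
#'
#' @param value Numeric value(s) in reduced units (`to_physical`) or physical
#'   units (`from_physical`).
#' @param kind One of `"length"` (nm), `"area"` (nm^2), `"time"` (ps),
#'   `"energy"` (J), `"energy_kJmol"` (kJ/mol), `"tension"` (mN/m).
#' @param units A [dpd_units()] object.
#' @return Converted numeric value(s).
#' @export
#' @examples
#' to_physical(1, "length")        # 0.71 nm
#' to_physical(23, "tension")      # K_A = 23 kBT/r0^2 in mN/m (~188)
#' from_physical(0.66, "area")     # back to r0^2
to_physical <- function(value, kind, units = dpd_units()) {
  value * unit_factor(kind, units)
}

#' @rdname to_physical
#' @export
from_physical <- function(value, kind, units = dpd_units()) {
  value / unit_factor(kind, units)
}
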