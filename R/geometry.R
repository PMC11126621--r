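# Sensor geometry: a main duct of cross-section S1 carrying, per unit cell, a
# closed side branch (length d2, cross-section S2) and an open side branch
# (length d3, cross-section S3) at the same axial position.  Each unit cell is
# a symmetric sandwich: half a duct of length d1/2, the combined shunt, and
# another half duct.  A defect guide of length dd and cross-section Sd sits at
# the centre, with n_cells unit cells forming the Bragg mirror on each side.
# The chain is terminated on both ends by semi-infinite ducts of cross-section
# S1.

#' Define the sensor geometry
#'
#' All lengths and cross-sections are stored in SI units (m, m^2).  Paper-style
#' centimetre inputs are accepted via `units = "cm"` (lengths in cm, areas in
#' cm^2).
#'
#' @param d1 Main-duct length per unit cell.
#' @param d2 Closed-branch length.
#' @param d3 Open-branch length.
#' @param dd Defect-guide length.
#' @param S1 Main-duct cross-section.
#' @param S2 Closed-branch cross-section.
#' @param S3 Open-branch cross-section.
#' @param Sd Defect-guide cross-section.
#' @param n_cells Number of unit cells in each Bragg mirror (per side of the
#'   defect); a positive integer.
#' @param units `"m"` (lengths m, areas m^2) or `"cm"` (lengths cm, areas
#'   cm^2).
#'
#' @return An object of class `sensor_geometry`.  The lattice period used in
#'   the Bloch phase `cos(K d)` is `d1`.
#' @examples
#' sensor_geometry(d1 = 10, d2 = 6, d3 = 6, dd = 33,
#'                 S1 = 1, S2 = 0.9, S3 = 0.9, Sd = 1, units = "cm")
#' @export
sensor_geometry <- function(d1, d2, d3, dd, S1, S2, S3, Sd,
                            n_cells = 10, units = c("m", "cm")) {
  units <- match.arg(units)
  vals <- c(d1 = d1, d2 = d2, d3 = d3, dd = dd,
            S1 = S1, S2 = S2, S3 = S3, Sd = Sd)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all lengths and cross-sections must be positive and finite",
         call. = FALSE)
  }
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1 ||
      n_cells != round(n_cells)) {
    stop("'n_cells' must be a positive integer", call. = FALSE)
  }
  if (units == "cm") {
    vals[c("d1", "d2", "d3", "dd")] <- vals[c("d1", "d2", "d3", "dd")] / 100
    vals[c("S1", "S2", "S3", "Sd")] <- vals[c("S1", "S2", "S3", "Sd")] / 1e4
  }
  structure(c(as.list(vals), list(n_cells = as.integer(n_cells))),
            class = "sensor_geometry")
}

#' @export
print.sensor_geometry <- function(x, ...) {
  cat("<sensor_geometry> (SI units)\n")
  cat(sprintf("  duct per cell   d1 = %g m, S1 = %g m^2\n", x$d1, x$S1))
  cat(sprintf("  closed branch   d2 = %g m, S2 = %g m^2\n", x$d2, x$S2))
  cat(sprintf("  open branch     d3 = %g m, S3 = %g m^2\n", x$d3, x$S3))
  cat(sprintf("  defect guide    dd = %g m, Sd = %g m^2\n", x$dd, x$Sd))
  cat(sprintf("  mirror cells per side: %d\n", x$n_cells))
  invisible(x)
}

#' Reference geometries of the breath-CO2 sensor
#'
#' `initial_geometry()` is the starting design: `d1 = 10` cm, `d2 = d3 = 6` cm,
#' `dd = 33` cm, `S1 = Sd = 1` cm^2, `S2 = S3 = 0.9` cm^2, ten mirror cells per
#' side.  `optimized_geometry()` is the design after one-parameter
#' optimisation: identical except `d1 = 20` cm and `dd = 100` cm.
#'
#' @return A `sensor_geometry`.
#' @examples
#' initial_geometry()
#' optimized_geometry()
#' @export
initial_geometry <- function() {
  sensor_geometry(d1 = 10, d2 = 6, d3 = 6, dd = 33,
                  S1 = 1, S2 = 0.9, S3 = 0.9, Sd = 1,
                  n_cells = 10, units = "cm")
}

#' @rdname initial_geometry
#' @export
optimized_geometry <- function() {
  sensor_geometry(d1 = 20, d2 = 6, d3 = 6, dd = 100,
                  S1 = 1, S2 = 0.9, S3 = 0.9, Sd = 1,
                  n_cells = 10, units = "cm")
}

# replace one geometry field (value in SI units), used by sweeps
geometry_with <- function(geometry, parameter, value) {
  stopifnot(inherits(geometry, "sensor_geometry"))
  if (!parameter %in% c("d1", "d2", "d3", "dd", "S1", "S2", "S3", "Sd")) {
    stop("unknown geometry parameter: ", parameter, call. = FALSE)
  }
  if (!is.finite(value) || value <= 0) {
    stop("parameter value must be positive", call. = FALSE)
  }
  geometry[[parameter]] <- value
  geometry
}
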