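# Acoustic two-port transfer-matrix method (TMM).
#
# A duct segment of length L, impedance Z = rho*c/S, has the ABCD matrix
#
#     [ cos(kL)          j Z sin(kL) ]
#     [ j sin(kL)/Z      cos(kL)     ]
#
# with k = 2*pi*f/c.  A shunt of admittance y is [1 0; y 1].  The unit cell is
# the symmetric product duct(d1/2) . shunt(y_OC) . duct(d1/2), where y_OC is
# the combined admittance of the open branch, -j cot(k d3)/Z3, and the closed
# branch, +j tan(k d2)/Z2.  The defect guide is a plain duct of length dd.
# All matrices are unimodular (det = 1): the network is lossless and
# reciprocal, so the transmittance never exceeds 100%.
#
# The full chain is mirror cells ^ n  .  defect  .  mirror cells ^ n, fed and
# terminated by semi-infinite main ducts of admittance Y1 = S1/(rho*c).  The
# amplitude transmission coefficient is
#
#     t = 2 Y1 / ((A11 + A12 Y1) Y1 + (A21 + A22 Y1)),     T(%) = 100 |t|^2.
#
# Branch admittances have poles where sin(k d3) = 0 or cos(k d2) = 0; sampled
# frequencies that land on a pole (|.| < 1e-12) are nudged by a relative 1e-9
# so the lossless limit T -> 0 is returned instead of NaN.

# nudge frequencies off branch-admittance poles
.safe_frequencies <- function(f, geometry, medium) {
  k <- 2 * pi * f / medium$sound_speed
  bad <- abs(sin(k * geometry$d3)) < 1e-12 | abs(cos(k * geometry$d2)) < 1e-12
  if (any(bad)) f[bad] <- f[bad] * (1 + 1e-9) + 1e-12
  f
}

# Vectorised total-matrix entries over a frequency grid.  Returns the entries
# of the assembled chain matrix together with the duct admittance Y1.  With
# include_defect = FALSE the chain is the defect-free crystal of 2*n_cells
# unit cells.
.tmm_total <- function(f, geometry, medium, include_defect = TRUE) {
  g <- geometry
  c0 <- medium$sound_speed
  rho <- medium$density
  f <- .safe_frequencies(f, g, medium)
  k <- 2 * pi * f / c0
  Z1 <- rho * c0 / g$S1
  Z2 <- rho * c0 / g$S2
  Z3 <- rho * c0 / g$S3
  Zd <- rho * c0 / g$Sd

  y_oc <- 1i * tan(k * g$d2) / Z2 - 1i / (Z3 * tan(k * g$d3))

  # half-duct entries (A = D)
  a <- cos(k * g$d1 / 2)
  b <- 1i * Z1 * sin(k * g$d1 / 2)
  cc <- 1i * sin(k * g$d1 / 2) / Z1

  # unit cell: duct(d1/2) . shunt . duct(d1/2)
  m11 <- a + b * y_oc
  m21 <- cc + a * y_oc
  u11 <- m11 * a + b * cc
  u12 <- m11 * b + b * a
  u21 <- m21 * a + a * cc
  u22 <- m21 * b + a * a

  # mirror: unit cell ^ n_cells
  one <- rep(1 + 0i, length(f))
  zero <- rep(0 + 0i, length(f))
  p11 <- one; p12 <- zero; p21 <- zero; p22 <- one
  for (i in seq_len(g$n_cells)) {
    n11 <- p11 * u11 + p12 * u21
    n12 <- p11 * u12 + p12 * u22
    n21 <- p21 * u11 + p22 * u21
    n22 <- p21 * u12 + p22 * u22
    p11 <- n11; p12 <- n12; p21 <- n21; p22 <- n22
  }

  if (include_defect) {
    ad <- cos(k * g$dd)
    bd <- 1i * Zd * sin(k * g$dd)
    cd <- 1i * sin(k * g$dd) / Zd
    q11 <- p11 * ad + p12 * cd
    q12 <- p11 * bd + p12 * ad
    q21 <- p21 * ad + p22 * cd
    q22 <- p21 * bd + p22 * ad
  } else {
    q11 <- p11; q12 <- p12; q21 <- p21; q22 <- p22
  }
  t11 <- q11 * p11 + q12 * p21
  t12 <- q11 * p12 + q12 * p22
  t21 <- q21 * p11 + q22 * p21
  t22 <- q21 * p12 + q22 * p22

  list(t11 = t11, t12 = t12, t21 = t21, t22 = t22,
       Y1 = g$S1 / (rho * c0), f = f)
}

# normalised transmission denominator A11 + A12*Y1 + A21/Y1 + A22;
# T = 400 / |.|^2, and its real part (= A11 + A22 for this lossless network)
# vanishes at a symmetric resonance.
.tmm_denominator <- function(f, geometry, medium, include_defect = TRUE) {
  m <- .tmm_total(f, geometry, medium, include_defect)
  m$t11 + m$t12 * m$Y1 + m$t21 / m$Y1 + m$t22
}

#' Characteristic duct impedance
#'
#' `Z = rho * c / S`; its reciprocal is the duct admittance `Y = S / (rho c)`.
#'
#' @param medium An [acoustic_medium] (or mixture/species coercible via
#'   [effective_medium()]).
#' @param area Duct cross-section in m^2 (> 0).
#' @return Impedance in Pa s / m^3.
#' @examples
#' duct_impedance(air_medium(), 1e-4)
#' @export
duct_impedance <- function(medium, area) {
  medium <- effective_medium(medium)
  if (!is.numeric(area) || any(area <= 0) || any(!is.finite(area))) {
    stop("'area' must be positive", call. = FALSE)
  }
  medium$density * medium$sound_speed / area
}

#' ABCD matrix of a plain duct segment
#'
#' @param f Frequency in Hz (scalar, > 0).
#' @param length Segment length in m.
#' @param medium An [acoustic_medium].
#' @param area Cross-section in m^2.
#' @return A 2x2 complex matrix with determinant 1.
#' @export
duct_matrix <- function(f, length, medium, area) {
  medium <- effective_medium(medium)
  stopifnot(length(f) == 1L, f > 0, length >= 0)
  k <- 2 * pi * f / medium$sound_speed
  Z <- duct_impedance(medium, area)
  matrix(c(cos(k * length), 1i * sin(k * length) / Z,
           1i * Z * sin(k * length), cos(k * length)),
         nrow = 2, ncol = 2)
}

#' Shunt admittances of the side branches
#'
#' The open branch (length `d3`, cross-section `S3`) presents
#' `y_O = -j cot(k d3) / Z3`; the closed branch (length `d2`, `S2`) presents
#' `y_C = +j tan(k d2) / Z2`; the combined load is their sum
#' `y_OC = y_O + y_C`.  All are purely imaginary: the branches are lossless.
#' A frequency landing on a branch pole is nudged, see Details in
#' [transmittance()].
#'
#' @param f Frequencies in Hz (vectorised, > 0).
#' @param geometry A [sensor_geometry].
#' @param medium An [acoustic_medium].
#' @return Complex admittance(s).
#' @examples
#' g <- initial_geometry()
#' open_branch_admittance(1000, g, air_medium())
#' @export
open_branch_admittance <- function(f, geometry, medium) {
  medium <- effective_medium(medium)
  stopifnot(all(f > 0))
  f <- .safe_frequencies(f, geometry, medium)
  k <- 2 * pi * f / medium$sound_speed
  Z3 <- duct_impedance(medium, geometry$S3)
  -1i / (Z3 * tan(k * geometry$d3))
}

#' @rdname open_branch_admittance
#' @export
closed_branch_admittance <- function(f, geometry, medium) {
  medium <- effective_medium(medium)
  stopifnot(all(f > 0))
  f <- .safe_frequencies(f, geometry, medium)
  k <- 2 * pi * f / medium$sound_speed
  Z2 <- duct_impedance(medium, geometry$S2)
  1i * tan(k * geometry$d2) / Z2
}

#' @rdname open_branch_admittance
#' @export
combined_admittance <- function(f, geometry, medium) {
  open_branch_admittance(f, geometry, medium) +
    closed_branch_admittance(f, geometry, medium)
}

#' Transfer matrix of one unit cell
#'
#' Symmetric product `duct(d1/2) . shunt(y_OC) . duct(d1/2)`.
#'
#' @inheritParams open_branch_admittance
#' @param f Frequency in Hz (scalar).
#' @return A 2x2 complex matrix with determinant 1.
#' @export
unit_cell_matrix <- function(f, geometry, medium) {
  medium <- effective_medium(medium)
  stopifnot(length(f) == 1L, f > 0)
  h <- duct_matrix(f, geometry$d1 / 2, medium, geometry$S1)
  y <- combined_admittance(f, geometry, medium)
  shunt <- matrix(c(1 + 0i, y, 0i, 1 + 0i), nrow = 2, ncol = 2)
  h %*% shunt %*% h
}

#' Transfer matrix of the defect guide
#'
#' A plain duct of length `dd` and cross-section `Sd`: the product of the two
#' half-length (`dd/2`) segment matrices.
#'
#' @inheritParams unit_cell_matrix
#' @return A 2x2 complex matrix with determinant 1.
#' @export
defect_cell_matrix <- function(f, geometry, medium) {
  medium <- effective_medium(medium)
  half <- duct_matrix(f, geometry$dd / 2, medium, geometry$Sd)
  half %*% half
}

#' Transfer matrix of the full sensor chain
#'
#' `unit_cell ^ n_cells . defect . unit_cell ^ n_cells`.
#'
#' @inheritParams unit_cell_matrix
#' @param include_defect If `FALSE`, the defect guide is omitted and the chain
#'   is the defect-free crystal of `2 * n_cells` unit cells.
#' @return A 2x2 complex matrix with determinant 1.
#' @export
assemble_total_matrix <- function(f, geometry, medium, include_defect = TRUE) {
  medium <- effective_medium(medium)
  u <- unit_cell_matrix(f, geometry, medium)
  p <- diag(2) + 0i
  for (i in seq_len(geometry$n_cells)) p <- p %*% u
  if (include_defect) {
    p %*% defect_cell_matrix(f, geometry, medium) %*% p
  } else {
    p %*% p
  }
}

#' Transmittance of the sensor
#'
#' Power transmittance in percent, `T = 100 |t|^2` with
#' `t = 2 Y1 / ((A11 + A12 Y1) Y1 + (A21 + A22 Y1))`, where `A` is the
#' assembled chain matrix and `Y1 = S1/(rho c)` the admittance of the
#' semi-infinite terminating ducts.
#'
#' @details
#' The network is lossless, so `0 <= T <= 100` at every frequency.  At a branch
#' resonance (`sin(k d3) = 0` or `cos(k d2) = 0`) the shunt admittance diverges
#' and the duct is acoustically shorted; such frequencies are nudged by one
#' part in 1e9 and return the limiting value `T -> 0` rather than `NaN`.
#'
#' @inheritParams open_branch_admittance
#' @param include_defect If `FALSE`, compute the defect-free crystal.
#' @return Transmittance(s) in percent, same length as `f`.
#' @examples
#' transmittance(c(500, 1000, 1887.6), initial_geometry(), air_medium())
#' @export
transmittance <- function(f, geometry, medium, include_defect = TRUE) {
  medium <- effective_medium(medium)
  stopifnot(all(is.finite(f)), all(f > 0))
  den <- .tmm_denominator(f, geometry, medium, include_defect)
  400 / Mod(den)^2
}

#' Transmittance spectrum on a uniform frequency grid
#'
#' @inheritParams transmittance
#' @param f_start,f_stop Scan limits in Hz, `0 < f_start < f_stop`.
#' @param step Grid step in Hz (default 0.05, the figure-resolution grid).
#'   Ignored when `n_samples` is given.
#' @param n_samples Optional number of samples (>= 2) overriding `step`.
#' @return A data frame of class `pnc_spectrum` with columns `frequency` (Hz)
#'   and `transmittance` (percent).
#' @examples
#' sp <- transmittance_spectrum(initial_geometry(), air_medium(),
#'                              f_start = 100, f_stop = 500, step = 1)
#' @export
transmittance_spectrum <- function(geometry, medium, f_start = 0.1,
                                   f_stop = 3000, step = 0.05,
                                   n_samples = NULL, include_defect = TRUE) {
  medium <- effective_medium(medium)
  stopifnot(f_start > 0, f_stop > f_start)
  f <- if (is.null(n_samples)) {
    seq(f_start, f_stop, by = step)
  } else {
    stopifnot(n_samples >= 2)
    seq(f_start, f_stop, length.out = n_samples)
  }
  out <- data.frame(frequency = f,
                    transmittance = transmittance(f, geometry, medium,
                                                  include_defect))
  attr(out, "medium") <- medium
  class(out) <- c("pnc_spectrum", "data.frame")
  out
}

#' @export
print.pnc_spectrum <- function(x, ...) {
  cat(sprintf("<pnc_spectrum> %d samples, %.6g-%.6g Hz, max T = %.3f%%\n",
              nrow(x), min(x$frequency), max(x$frequency),
              max(x$transmittance)))
  invisible(x)
}

#' @export
plot.pnc_spectrum <- function(x, ...) {
  graphics::plot(x$frequency, x$transmittance, type = "l",
                 xlab = "Frequency (Hz)", ylab = "Transmittance (%)",
                 ylim = c(0, 100), ...)
  invisible(x)
}

#' Write a spectrum as two-column delimited text
#'
#' @param spectrum A `pnc_spectrum`.
#' @param path File path, or `""` for standard output.
#' @param header Optional named list written as `# key: value` comment lines.
#' @return Invisibly, the spectrum.
#' @export
write_spectrum <- function(spectrum, path = "", header = NULL) {
  stopifnot(inherits(spectrum, "pnc_spectrum"))
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  for (key in names(header)) {
    writeLines(sprintf("# %s: %s", key, format(header[[key]])), con)
  }
  out <- data.frame(frequency_Hz = spectrum$frequency,
                    T_percent = spectrum$transmittance)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(spectrum)
}
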