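# Bloch dispersion of the infinite periodic waveguide (Green-method form).
#
# The interface-response (Green surface) functions of the two resonators on
# one cell are, with y_i = S_i / (rho c),
#
#     g_c^{-1} = -j y2 tan(k d2)        (closed branch)
#     g_o^{-1} = +j y3 cot(k d3)        (open branch)
#
# and their sum g_R^{-1} = g_c^{-1} + g_o^{-1} equals minus the combined shunt
# admittance y_OC of the transfer-matrix construction.  The dispersion relation
# of the infinite crystal is
#
#     cos(K d) = cos(k d1) + (j/2) Z1 y_OC sin(k d1),
#
# with d = d1 the lattice period, K the Bloch wavevector and k = 2 pi f / c.
# Because y_OC is purely imaginary the right-hand side is real; |cos(Kd)| > 1
# marks a forbidden frequency (phononic band gap).

#' Inverse Green surface functions of the shunt resonators
#'
#' `green_inverse_closed()` returns `-j y2 tan(k d2)`; `green_inverse_open()`
#' returns `+j y3 cot(k d3)` (written with the open-branch constants `y3`,
#' `d3`, and with the sign that makes the closed + open sum equal minus the
#' combined shunt admittance of [combined_admittance()]).  Both are purely
#' imaginary.
#'
#' @inheritParams open_branch_admittance
#' @return Complex value(s), purely imaginary.
#' @export
green_inverse_closed <- function(f, geometry, medium) {
  medium <- effective_medium(medium)
  stopifnot(all(f > 0))
  f <- .safe_frequencies(f, geometry, medium)
  k <- 2 * pi * f / medium$sound_speed
  y2 <- geometry$S2 / (medium$density * medium$sound_speed)
  -1i * y2 * tan(k * geometry$d2)
}

#' @rdname green_inverse_closed
#' @export
green_inverse_open <- function(f, geometry, medium) {
  medium <- effective_medium(medium)
  stopifnot(all(f > 0))
  f <- .safe_frequencies(f, geometry, medium)
  k <- 2 * pi * f / medium$sound_speed
  y3 <- geometry$S3 / (medium$density * medium$sound_speed)
  1i * y3 / tan(k * geometry$d3)
}

#' Bloch dispersion value cos(Kd)
#'
#' @inheritParams open_branch_admittance
#' @return Real value(s) of `cos(K d)`; `|value| > 1` marks a band gap.
#' @examples
#' bloch_dispersion(c(200, 1200, 1887), initial_geometry(), air_medium())
#' @export
bloch_dispersion <- function(f, geometry, medium) {
  medium <- effective_medium(medium)
  stopifnot(all(f > 0))
  f <- .safe_frequencies(f, geometry, medium)
  k <- 2 * pi * f / medium$sound_speed
  Z1 <- duct_impedance(medium, geometry$S1)
  y_oc <- combined_admittance(f, geometry, medium)
  val <- cos(k * geometry$d1) + 0.5i * Z1 * y_oc * sin(k * geometry$d1)
  # y_OC is purely imaginary, so the dispersion value is real
  stopifnot(all(abs(Im(val)) < 1e-9 * pmax(1, abs(Re(val)))))
  Re(val)
}

#' Band structure of the infinite crystal
#'
#' @inheritParams band_gaps
#' @return A data frame of class `pnc_bands` with columns `frequency`,
#'   `cos_Kd` and `in_gap` (`|cos_Kd| > 1`).
#' @export
band_structure <- function(geometry, medium, f_start = 0.1, f_stop = 3000,
                           resolution = 0.25) {
  medium <- effective_medium(medium)
  stopifnot(f_start > 0, f_stop > f_start, resolution > 0)
  f <- seq(f_start, f_stop, by = resolution)
  ck <- bloch_dispersion(f, geometry, medium)
  out <- data.frame(frequency = f, cos_Kd = ck, in_gap = abs(ck) > 1)
  class(out) <- c("pnc_bands", "data.frame")
  out
}

#' @export
print.pnc_bands <- function(x, ...) {
  cat(sprintf("<pnc_bands> %d samples, %.6g-%.6g Hz, %.1f%% in gaps\n",
              nrow(x), min(x$frequency), max(x$frequency),
              100 * mean(x$in_gap)))
  invisible(x)
}

#' @export
plot.pnc_bands <- function(x, ...) {
  graphics::plot(x$frequency, pmax(pmin(x$cos_Kd, 2), -2), type = "l",
                 xlab = "Frequency (Hz)", ylab = "cos(Kd)  (clipped at +/-2)",
                 ...)
  graphics::abline(h = c(-1, 1), lty = 2)
  invisible(x)
}

#' Phononic band gaps
#'
#' Scans `cos(Kd)` on a uniform grid and returns the maximal contiguous
#' intervals where `|cos(Kd)| > 1`.  Interior gap edges are refined by
#' bisection on `|cos(Kd)| - 1` to `edge_tol` Hz; a gap truncated by the scan
#' limits keeps the limit as its edge.
#'
#' @param geometry A [sensor_geometry].
#' @param medium An [acoustic_medium] (or coercible).
#' @param f_start,f_stop Scan limits in Hz.
#' @param resolution Scan grid step in Hz.
#' @param edge_tol Bisection tolerance for gap edges, Hz.
#' @return A data frame of class `band_gaps` with columns `index`, `f_lower`
#'   and `f_upper` (Hz), ordered by frequency; zero rows if no gap lies in
#'   range.
#' @examples
#' band_gaps(initial_geometry(), air_medium(), f_stop = 2100)
#' @export
band_gaps <- function(geometry, medium, f_start = 0.1, f_stop = 3000,
                      resolution = 0.25, edge_tol = 1e-3) {
  medium <- effective_medium(medium)
  stopifnot(f_start > 0, f_stop > f_start, resolution > 0)
  f <- seq(f_start, f_stop, by = resolution)
  excess <- abs(bloch_dispersion(f, geometry, medium)) - 1
  in_gap <- excess > 0
  runs <- rle(in_gap)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  gap_runs <- which(runs$values)
  if (!length(gap_runs)) {
    out <- data.frame(index = integer(), f_lower = numeric(),
                      f_upper = numeric())
    class(out) <- c("band_gaps", "data.frame")
    return(out)
  }
  gfun <- function(x) abs(bloch_dispersion(x, geometry, medium)) - 1
  lower <- upper <- numeric(length(gap_runs))
  for (j in seq_along(gap_runs)) {
    i0 <- starts[gap_runs[j]]
    i1 <- ends[gap_runs[j]]
    lower[j] <- if (i0 == 1L) f[1] else {
      stats::uniroot(gfun, c(f[i0 - 1L], f[i0]), tol = edge_tol)$root
    }
    upper[j] <- if (i1 == length(f)) f[length(f)] else {
      stats::uniroot(gfun, c(f[i1], f[i1 + 1L]), tol = edge_tol)$root
    }
  }
  out <- data.frame(index = seq_along(gap_runs), f_lower = lower,
                    f_upper = upper)
  class(out) <- c("band_gaps", "data.frame")
  out
}

#' Write band structure or gap list as delimited text
#'
#' @param x A `pnc_bands` or `band_gaps` object.
#' @param path File path, or `""` for standard output.
#' @return Invisibly, `x`.
#' @export
write_bands <- function(x, path = "") {
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  if (inherits(x, "pnc_bands")) {
    out <- data.frame(frequency_Hz = x$frequency, cos_Kd = x$cos_Kd,
                      in_gap = as.integer(x$in_gap))
  } else if (inherits(x, "band_gaps")) {
    out <- data.frame(index = x$index, f_low_Hz = x$f_lower,
                      f_high_Hz = x$f_upper)
  } else {
    stop("'x' must be a pnc_bands or band_gaps object", call. = FALSE)
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
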