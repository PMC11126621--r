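# One-parameter geometry sweeps: recompute the full metrics report while one
# duct length or cross-section varies, and select the optimum value.  Sweep
# rows where the resonant mode leaves the operating band (or drops below the
# detection threshold) are kept with peak_found = FALSE rather than failing
# the sweep.

#' Specify a one-parameter geometry sweep
#'
#' @param parameter One of `"d1"`, `"d2"`, `"d3"`, `"dd"`, `"S1"`, `"S2"`,
#'   `"S3"`, `"Sd"`.
#' @param values Numeric vector (>= 2 values, all positive) of parameter
#'   values.
#' @param geometry Base [sensor_geometry]; the swept field is replaced per row.
#' @param units `"m"` (lengths m, areas m^2) or `"cm"` (lengths cm, areas
#'   cm^2) for `values`.
#' @param mixture_low,mixture_high Mixture pair for the sensitivity and shift
#'   metrics; defaults to the enrichment endpoints 0 and 100 units.
#' @param f_window Operating frequency window passed to
#'   [locate_defect_peak()].
#' @param threshold Minimum peak transmittance (percent) for `peak_found`.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(parameter, values, geometry = optimized_geometry(),
                       units = c("m", "cm"),
                       mixture_low = deb_mixture(0),
                       mixture_high = deb_mixture(100),
                       f_window = c(1700, 1910), threshold = 1) {
  parameter <- match.arg(parameter,
                         c("d1", "d2", "d3", "dd", "S1", "S2", "S3", "Sd"))
  units <- match.arg(units)
  values <- as.numeric(values)
  if (length(values) < 2L || any(!is.finite(values)) || any(values <= 0)) {
    stop("'values' must be >= 2 positive numbers", call. = FALSE)
  }
  if (units == "cm") {
    values <- if (startsWith(parameter, "d")) values / 100 else values / 1e4
  }
  structure(
    list(parameter = parameter, values = values, geometry = geometry,
         mixture_low = mixture_low, mixture_high = mixture_high,
         f_window = f_window, threshold = threshold),
    class = "sweep_spec"
  )
}

#' Run a one-parameter sweep
#'
#' One row per parameter value, each computed by the full metrics pipeline
#' ([sensor_metrics()]).  Rows are independent: permuting `values` permutes
#' the rows.  A value for which no defect peak is found inside the operating
#' window carries `peak_found = FALSE` and `NA` metrics.
#'
#' @param spec A [sweep_spec].
#' @return A data frame of class `pnc_sweep` with columns `value` (SI units),
#'   `peak_found`, `f_R`, `T_peak`, `fwhm`, `S`, `FoM`, `Q`, `LoD`, `SNR`,
#'   `RS`.
#' @examples
#' \donttest{
#' sp <- sweep_spec("d3", c(5.5, 6.0, 6.5), units = "cm")
#' run_sweep(sp)
#' }
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- lapply(spec$values, function(v) {
    g <- geometry_with(spec$geometry, spec$parameter, v)
    res <- tryCatch(
      sensor_metrics(g, spec$mixture_low, spec$mixture_high,
                     f_window = spec$f_window, threshold = spec$threshold),
      error = function(e) NULL
    )
    if (is.null(res)) {
      data.frame(value = v, peak_found = FALSE, f_R = NA_real_,
                 T_peak = NA_real_, fwhm = NA_real_, S = NA_real_,
                 FoM = NA_real_, Q = NA_real_, LoD = NA_real_,
                 SNR = NA_real_, RS = NA_real_)
    } else {
      data.frame(value = v, peak_found = TRUE, f_R = res$f_R,
                 T_peak = res$T_peak, fwhm = res$fwhm, S = res$S,
                 FoM = res$FoM, Q = res$Q, LoD = res$LoD, SNR = res$SNR,
                 RS = res$RS)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "parameter") <- spec$parameter
  class(out) <- c("pnc_sweep", "data.frame")
  out
}

#' @export
print.pnc_sweep <- function(x, ...) {
  cat(sprintf("<pnc_sweep> parameter %s, %d values (%d with peak)\n",
              attr(x, "parameter"), nrow(x), sum(x$peak_found)))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Select the optimum parameter value from a sweep
#'
#' Default criterion: the row with maximal figure of merit among rows whose
#' peak was found and whose peak transmittance is at least `t_floor` percent;
#' ties (within `tie_tol` relative FoM) are broken toward higher quality
#' factor.  The transmittance floor is a convention: it discards designs whose
#' resonance is too weak to read out, and 50% reproduces every selection of
#' the one-parameter studies shipped with the package.
#'
#' @param rows A `pnc_sweep` data frame from [run_sweep()].
#' @param criterion Metric to maximise, `"FoM"` (default), `"Q"`, `"S"`, or
#'   `"T_peak"`; or `"fwhm"`/`"LoD"`/`"RS"` to minimise.
#' @param t_floor Minimum acceptable peak transmittance in percent.
#' @param tie_tol Relative tolerance within which two criterion values count
#'   as tied.
#' @return The selected parameter value (SI units), with the winning row as
#'   attribute `"row"`.
#' @export
select_optimum <- function(rows, criterion = "FoM", t_floor = 50,
                           tie_tol = 1e-6) {
  stopifnot(inherits(rows, "data.frame"))
  criterion <- match.arg(criterion,
                         c("FoM", "Q", "S", "T_peak", "fwhm", "LoD", "RS"))
  ok <- rows$peak_found & rows$T_peak >= t_floor
  if (!any(ok)) stop("no sweep row qualifies (peak found and T_peak >= floor)",
                     call. = FALSE)
  cand <- rows[ok, , drop = FALSE]
  score <- cand[[criterion]]
  if (criterion %in% c("fwhm", "LoD", "RS")) score <- -score
  best <- max(score)
  tied <- which(score >= best - tie_tol * abs(best))
  if (length(tied) > 1L) tied <- tied[which.max(cand$Q[tied])]
  out <- cand$value[tied]
  attr(out, "row") <- cand[tied, , drop = FALSE]
  out
}

#' Printed sweep grids of the one-parameter studies
#'
#' The value lists (in SI units) used by the shipped one-parameter studies of
#' each geometry field around the optimised design.
#'
#' @param parameter Geometry field name.
#' @return Numeric vector of values in m or m^2.
#' @export
default_sweep_values <- function(parameter) {
  switch(parameter,
    dd = c(20, 60, 100, 150) / 100,
    d1 = c(10, 15, 20, 25, 30) / 100,
    d2 = c(5.8, 6.0, 6.5, 7.0) / 100,
    d3 = c(5.5, 6.0, 6.5, 7.0, 7.5) / 100,
    Sd = c(0.90, 0.95, 1.00, 1.05, 1.10) / 1e4,
    S1 = c(0.90, 0.95, 1.00, 1.05, 1.10) / 1e4,
    S2 = c(0.7, 0.8, 0.9, 1.0, 1.1) / 1e4,
    S3 = c(0.7, 0.8, 0.9, 1.0, 1.1) / 1e4,
    stop("unknown parameter: ", parameter, call. = FALSE)
  )
}
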