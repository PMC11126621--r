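# Defect-resonance localisation and sensor performance metrics.
#
# The defect mode is an extremely narrow transmission resonance inside a band
# gap (quality factors up to ~1e7 for the designs studied here), far too
# narrow for any practical uniform grid.  The locator exploits the structure
# of the lossless, mirror-symmetric chain: the normalised transmission
# denominator A11 + A12*Y1 + A21/Y1 + A22 has real part A11 + A22 and
# imaginary part (Im A12) Y1 + (Im A21)/Y1; at a symmetric resonance the real
# part crosses zero while inside a gap it otherwise grows like the Bragg
# attenuation.  Zero crossings of A11 + A22 on a coarse grid are therefore a
# robust, resolution-independent detector of defect modes.  Each crossing is
# refined by bisection, after which the transmittance maximum is polished by
# iterative grid shrinking and the full width at half maximum is resolved by
# bisection on each flank.

# real part of the normalised transmission denominator (= A11 + A22)
.denominator_trace <- function(f, geometry, medium) {
  Re(.tmm_denominator(f, geometry, medium))
}

# refine the transmittance maximum near f0 by iterative grid shrinking
.polish_peak <- function(f0, geometry, medium, halfwidth = 0.05,
                         f_tol = 1e-8) {
  lo <- f0 - halfwidth
  hi <- f0 + halfwidth
  repeat {
    fs <- seq(lo, hi, length.out = 41L)
    tv <- transmittance(fs, geometry, medium)
    i <- which.max(tv)
    lo <- fs[max(1L, i - 1L)]
    hi <- fs[min(41L, i + 1L)]
    if (hi - lo < f_tol) break
  }
  list(f_R = fs[i], T_peak = tv[i])
}

# search one interval for symmetric-resonance candidates
.peak_candidates <- function(geometry, medium, lo, hi, scan_step) {
  if (hi - lo < 4 * scan_step) return(NULL)
  fs <- seq(lo, hi, by = scan_step)
  tr <- .denominator_trace(fs, geometry, medium)
  cross <- which(diff(sign(tr)) != 0)
  out <- NULL
  for (i in cross) {
    root <- stats::uniroot(function(x) .denominator_trace(x, geometry, medium),
                           c(fs[i], fs[i + 1L]), tol = 1e-12)$root
    pk <- .polish_peak(root, geometry, medium, halfwidth = scan_step)
    out <- rbind(out, c(f_R = pk$f_R, T_peak = pk$T_peak))
  }
  out
}

#' Locate the defect resonance inside a band gap
#'
#' Finds the transmission peak created by the defect guide inside a phononic
#' band gap.  Candidate resonances are detected as zero crossings of the trace
#' `A11 + A22` of the assembled chain matrix (which vanishes at a resonance of
#' this mirror-symmetric lossless network) on a coarse grid, refined by
#' bisection and polished by iterative grid shrinking until the peak frequency
#' is stable to well below 1e-5 Hz.  Among candidates above `threshold`, the
#' one with the highest peak transmittance is returned (ties within one
#' percentage point go to the narrower peak).
#'
#' @param geometry A [sensor_geometry].
#' @param medium An [acoustic_medium], [gas_mixture] or [gas_species].
#' @param gap Search gap: either a length-2 numeric interval in Hz, or a
#'   single integer indexing the gaps returned by [band_gaps()] (counted from
#'   the lowest frequency).  Ignored when `f_window` is given.
#' @param f_window Alternative to `gap`: a length-2 frequency window in Hz;
#'   every band gap overlapping the window is searched.
#' @param threshold Minimum peak transmittance in percent (default 1) for a
#'   candidate to count as a defect peak.
#' @param scan_step Coarse scan step in Hz used for crossing detection.
#' @param f_stop Upper limit of the band-gap scan used to resolve `gap` /
#'   `f_window`.
#' @return An object of class `defect_peak`: a list with `f_R` (peak frequency,
#'   Hz), `T_peak` (percent), `fwhm` (Hz), and `gap` (the searched interval).
#' @examples
#' \donttest{
#' locate_defect_peak(initial_geometry(), air_medium(), gap = 3)
#' }
#' @export
locate_defect_peak <- function(geometry, medium, gap = NULL, f_window = NULL,
                               threshold = 1, scan_step = 0.05,
                               f_stop = 3000) {
  medium <- effective_medium(medium)
  intervals <- NULL
  if (!is.null(f_window)) {
    stopifnot(length(f_window) == 2L, f_window[1] < f_window[2])
    gaps <- band_gaps(geometry, medium, f_stop = f_stop)
    keep <- gaps$f_upper > f_window[1] & gaps$f_lower < f_window[2]
    gaps <- gaps[keep, , drop = FALSE]
    if (!nrow(gaps)) {
      stop("no band gap overlaps the requested frequency window",
           call. = FALSE)
    }
    intervals <- cbind(pmax(gaps$f_lower, f_window[1]),
                       pmin(gaps$f_upper, f_window[2]))
  } else if (!is.null(gap)) {
    if (length(gap) == 1L) {
      gaps <- band_gaps(geometry, medium, f_stop = f_stop)
      if (gap < 1 || gap > nrow(gaps)) {
        stop(sprintf("gap index %d out of range (%d gaps found below %g Hz)",
                     as.integer(gap), nrow(gaps), f_stop), call. = FALSE)
      }
      intervals <- cbind(gaps$f_lower[gap], gaps$f_upper[gap])
    } else {
      stopifnot(length(gap) == 2L, gap[1] < gap[2])
      intervals <- cbind(gap[1], gap[2])
    }
  } else {
    stop("one of 'gap' or 'f_window' must be supplied", call. = FALSE)
  }

  cand <- NULL
  for (r in seq_len(nrow(intervals))) {
    margin <- min(0.5, 0.01 * (intervals[r, 2] - intervals[r, 1]))
    cand <- rbind(cand, .peak_candidates(geometry, medium,
                                         intervals[r, 1] + margin,
                                         intervals[r, 2] - margin, scan_step))
  }
  cand <- cand[cand[, "T_peak"] >= threshold, , drop = FALSE]
  if (is.null(cand) || !nrow(cand)) {
    stop("no defect peak above the transmittance threshold in the search gap",
         call. = FALSE)
  }
  best_t <- max(cand[, "T_peak"])
  near <- which(cand[, "T_peak"] >= best_t - 1)
  if (length(near) > 1L) {
    widths <- vapply(near, function(i) {
      peak_fwhm(geometry, medium, cand[i, "f_R"], cand[i, "T_peak"])
    }, numeric(1))
    pick <- near[which.min(widths)]
    width <- min(widths)
  } else {
    pick <- near
    width <- peak_fwhm(geometry, medium, cand[pick, "f_R"],
                       cand[pick, "T_peak"])
  }
  structure(
    list(f_R = unname(cand[pick, "f_R"]),
         T_peak = unname(cand[pick, "T_peak"]),
         fwhm = width,
         gap = c(min(intervals[, 1]), max(intervals[, 2]))),
    class = "defect_peak"
  )
}

#' @export
print.defect_peak <- function(x, ...) {
  cat(sprintf(
    "<defect_peak> f_R = %.5f Hz, T = %.3f%%, FWHM = %.4g Hz (Q = %.4g)\n",
    x$f_R, x$T_peak, x$fwhm, x$f_R / x$fwhm))
  invisible(x)
}

#' Full width at half maximum of a located peak
#'
#' Bisection on each flank for the crossings `T = T_peak / 2`, each resolved to
#' well below 1e-7 Hz.  The half level is taken relative to the peak
#' transmittance, not relative to 100%.
#'
#' @inheritParams locate_defect_peak
#' @param f_R Peak frequency in Hz.
#' @param T_peak Peak transmittance in percent.
#' @return Width in Hz.
#' @export
peak_fwhm <- function(geometry, medium, f_R, T_peak) {
  medium <- effective_medium(medium)
  half <- T_peak / 2
  gfun <- function(x) transmittance(x, geometry, medium) - half
  step <- 1e-7
  while (gfun(f_R - step) > 0) step <- step * 2
  left <- stats::uniroot(gfun, c(f_R - step, f_R), tol = 1e-11)$root
  step <- 1e-7
  while (gfun(f_R + step) > 0) step <- step * 2
  right <- stats::uniroot(gfun, c(f_R, f_R + step), tol = 1e-11)$root
  right - left
}

#' @rdname peak_fwhm
#' @param peak A `defect_peak` object (alternative interface).
#' @export
fwhm <- function(geometry, medium, peak) {
  stopifnot(inherits(peak, "defect_peak"))
  peak_fwhm(geometry, medium, peak$f_R, peak$T_peak)
}

#' Standing-wave resonance frequency of a guide
#'
#' `f = n c / (2 L)`: the n-th harmonic of a guide of length `L` filled with a
#' medium of sound speed `c`.  Used as a consistency predictor for the defect
#' resonance (the located peak tracks the sound speed in exactly this
#' proportional way), not as the peak locator.
#'
#' @param length Guide length in m.
#' @param n Harmonic number (positive integer).
#' @param sound_speed Sound speed in m/s.
#' @return Frequency in Hz.
#' @examples
#' standing_wave_frequency(1, 1, 340) # 170 Hz
#' @export
standing_wave_frequency <- function(length, n, sound_speed) {
  stopifnot(length > 0, sound_speed > 0, n >= 1, n == round(n))
  n * sound_speed / (2 * length)
}

#' Sensor sensitivity
#'
#' `S = |delta f_R| / |delta c|`: shift of the defect-peak frequency per unit
#' change of the sample's effective sound speed, in Hz m^-1 s.
#'
#' @param geometry A [sensor_geometry].
#' @param mixture_low,mixture_high Two media (mixtures or [acoustic_medium])
#'   whose sound speeds differ.
#' @param ... Passed to [locate_defect_peak()] (e.g. `gap` or `f_window`).
#' @return Sensitivity in Hz m^-1 s.
#' @export
sensitivity <- function(geometry, mixture_low, mixture_high, ...) {
  m_lo <- effective_medium(mixture_low)
  m_hi <- effective_medium(mixture_high)
  dc <- m_hi$sound_speed - m_lo$sound_speed
  if (abs(dc) < .Machine$double.eps * max(m_lo$sound_speed, 1)) {
    stop("the two media have identical sound speeds", call. = FALSE)
  }
  p_lo <- locate_defect_peak(geometry, m_lo, ...)
  p_hi <- locate_defect_peak(geometry, m_hi, ...)
  abs(p_hi$f_R - p_lo$f_R) / abs(dc)
}

#' Figure of merit, quality factor, detection limit, SNR and resolution
#'
#' The scalar sensor indicators: `FoM = S / FWHM` (m^-1 s),
#' `Q = f_R / FWHM` (dimensionless), `LoD = f_R / (20 S Q)` (m/s),
#' `SNR = delta_f / FWHM` (dimensionless; the deterministic shift-to-linewidth
#' ratio, not a measured noise figure) and the resolution measure
#' `RS = 2 FWHM / (3 SNR^0.25)`.
#'
#' @param S Sensitivity in Hz m^-1 s.
#' @param fwhm Full width at half maximum in Hz.
#' @param f_R Peak frequency in Hz.
#' @param Q Quality factor.
#' @param delta_f Peak shift in Hz over the measured concentration range.
#' @param snr Signal-to-noise ratio.
#' @return A single number.
#' @name sensor_indicators
NULL

#' @rdname sensor_indicators
#' @export
figure_of_merit <- function(S, fwhm) {
  stopifnot(S > 0, fwhm > 0)
  S / fwhm
}

#' @rdname sensor_indicators
#' @export
quality_factor <- function(f_R, fwhm) {
  stopifnot(f_R > 0, fwhm > 0)
  f_R / fwhm
}

#' @rdname sensor_indicators
#' @export
detection_limit <- function(f_R, S, Q) {
  stopifnot(f_R > 0, S > 0, Q > 0)
  f_R / (20 * S * Q)
}

#' @rdname sensor_indicators
#' @export
signal_to_noise <- function(delta_f, fwhm) {
  stopifnot(delta_f > 0, fwhm > 0)
  delta_f / fwhm
}

#' @rdname sensor_indicators
#' @export
resolution_rs <- function(fwhm, snr) {
  stopifnot(fwhm > 0, snr > 0)
  2 * fwhm / (3 * snr^0.25)
}

#' Complete sensor performance report
#'
#' Locates the defect peak for the baseline and the enriched mixture, resolves
#' the baseline linewidth, and assembles all indicators.  The shift `delta_f`
#' and speed difference `delta_c` are magnitudes over the supplied mixture
#' pair (by default the endpoints of the studied enrichment range, 0 and 100
#' units).
#'
#' @param geometry A [sensor_geometry].
#' @param mixture_low Baseline mixture (default [deb_mixture(0)][deb_mixture]).
#' @param mixture_high Enriched mixture (default `deb_mixture(100)`).
#' @param ... Passed to [locate_defect_peak()]; supply `gap` or `f_window` to
#'   select the operating band gap.
#' @return An object of class `sensor_metrics`: a list with `f_R`, `T_peak`,
#'   `fwhm`, `delta_f`, `delta_c`, `S`, `FoM`, `Q`, `LoD`, `SNR`, `RS` (all at
#'   the baseline mixture except the shift-based quantities).
#' @examples
#' \donttest{
#' sensor_metrics(optimized_geometry(), f_window = c(1700, 1910))
#' }
#' @export
sensor_metrics <- function(geometry, mixture_low = deb_mixture(0),
                           mixture_high = deb_mixture(100), ...) {
  m_lo <- effective_medium(mixture_low)
  m_hi <- effective_medium(mixture_high)
  dc <- abs(m_hi$sound_speed - m_lo$sound_speed)
  if (dc < .Machine$double.eps * max(m_lo$sound_speed, 1)) {
    stop("the two media have identical sound speeds", call. = FALSE)
  }
  p_lo <- locate_defect_peak(geometry, m_lo, ...)
  p_hi <- locate_defect_peak(geometry, m_hi, ...)
  df <- abs(p_hi$f_R - p_lo$f_R)
  S <- df / dc
  fom <- figure_of_merit(S, p_lo$fwhm)
  q <- quality_factor(p_lo$f_R, p_lo$fwhm)
  lod <- detection_limit(p_lo$f_R, S, q)
  snr <- signal_to_noise(df, p_lo$fwhm)
  rs <- resolution_rs(p_lo$fwhm, snr)
  structure(
    list(f_R = p_lo$f_R, T_peak = p_lo$T_peak, fwhm = p_lo$fwhm,
         f_R_high = p_hi$f_R, delta_f = df, delta_c = dc,
         S = S, FoM = fom, Q = q, LoD = lod, SNR = snr, RS = rs),
    class = "sensor_metrics"
  )
}

#' @export
print.sensor_metrics <- function(x, ...) {
  cat("<sensor_metrics>\n")
  cat(sprintf("  f_R     %.5f Hz   (enriched: %.5f Hz)\n", x$f_R, x$f_R_high))
  cat(sprintf("  T_peak  %.3f %%\n", x$T_peak))
  cat(sprintf("  FWHM    %.4g Hz\n", x$fwhm))
  cat(sprintf("  delta_f %.4f Hz over delta_c %.4f m/s\n",
              x$delta_f, x$delta_c))
  cat(sprintf("  S       %.4f Hz m^-1 s\n", x$S))
  cat(sprintf("  FoM     %.4g m^-1 s\n", x$FoM))
  cat(sprintf("  Q       %.4g\n", x$Q))
  cat(sprintf("  LoD     %.4g m/s\n", x$LoD))
  cat(sprintf("  SNR     %.4g\n", x$SNR))
  cat(sprintf("  RS      %.4g\n", x$RS))
  invisible(x)
}

#' One-row delimited export of a metrics report
#'
#' @param metrics A `sensor_metrics` object.
#' @param path File path, or `""` for standard output.
#' @param header Optional named list written as `# key: value` comment lines.
#' @return Invisibly, the metrics.
#' @export
write_metrics <- function(metrics, path = "", header = NULL) {
  stopifnot(inherits(metrics, "sensor_metrics"))
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  for (key in names(header)) {
    writeLines(sprintf("# %s: %s", key, format(header[[key]])), con)
  }
  out <- data.frame(f_R_Hz = metrics$f_R, T_peak_percent = metrics$T_peak,
                    FWHM_Hz = metrics$fwhm, S = metrics$S, FoM = metrics$FoM,
                    Q = metrics$Q, LoD = metrics$LoD, SNR = metrics$SNR,
                    RS = metrics$RS)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(metrics)
}

#' Linear CO2 calibration of the defect-peak frequency
#'
#' Ordinary least squares of the defect-peak frequency on the CO2 enrichment
#' level.  Either supply precomputed peak frequencies (`f_R_values`) or a
#' `geometry`, in which case the peaks are located for each enrichment level.
#'
#' @param enrichment_levels Numeric vector of enrichment levels (units of 0.01
#'   percentage point CO2); at least 3 distinct values.
#' @param f_R_values Optional peak frequencies in Hz, same length.
#' @param geometry A [sensor_geometry], required when `f_R_values` is missing.
#' @param ... Passed to [locate_defect_peak()] when peaks are computed here.
#' @return An object of class `pnc_calibration` wrapping the [stats::lm] fit,
#'   with `levels`, `f_R`, `slope` (Hz per enrichment unit), `intercept` (Hz),
#'   `r_squared` and `rss`.
#' @examples
#' calibration_fit(c(0, 50, 100), f_R_values = c(1800.0, 1797.2, 1794.4))
#' @export
calibration_fit <- function(enrichment_levels, f_R_values = NULL,
                            geometry = NULL, ...) {
  lv <- as.numeric(enrichment_levels)
  if (length(unique(lv)) < 3L) {
    stop("at least 3 distinct enrichment levels are required", call. = FALSE)
  }
  if (is.null(f_R_values)) {
    if (is.null(geometry)) {
      stop("supply either 'f_R_values' or a 'geometry'", call. = FALSE)
    }
    f_R_values <- vapply(lv, function(u) {
      locate_defect_peak(geometry, deb_mixture(u), ...)$f_R
    }, numeric(1))
  }
  stopifnot(length(f_R_values) == length(lv))
  dat <- data.frame(level = lv, f_R = as.numeric(f_R_values))
  fit <- stats::lm(f_R ~ level, data = dat)
  structure(
    list(fit = fit, levels = lv, f_R = dat$f_R,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = suppressWarnings(summary(fit)$r.squared),
         rss = sum(stats::residuals(fit)^2)),
    class = "pnc_calibration"
  )
}

#' @export
print.pnc_calibration <- function(x, ...) {
  cat("<pnc_calibration>\n")
  cat(sprintf("  f_R = %+.6g * level %+.6g   (Hz per enrichment unit)\n",
              x$slope, x$intercept))
  cat(sprintf("  R^2 = %.6f, RSS = %.4g, n = %d\n",
              x$r_squared, x$rss, length(x$levels)))
  invisible(x)
}

#' @export
coef.pnc_calibration <- function(object, ...) stats::coef(object$fit)

#' @export
predict.pnc_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  if (is.numeric(newdata)) newdata <- data.frame(level = newdata)
  stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.pnc_calibration <- function(object, ...) {
  stats::residuals(object$fit)
}

#' @export
summary.pnc_calibration <- function(object, ...) summary(object$fit, ...)

#' @export
plot.pnc_calibration <- function(x, ...) {
  graphics::plot(x$levels, x$f_R, xlab = "CO2 enrichment (units)",
                 ylab = "Resonant frequency (Hz)", ...)
  graphics::abline(x$fit)
  invisible(x)
}
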