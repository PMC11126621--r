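test_that("defect peak localisation reproduces the published resonances", {
  g <- initial_geometry()
  pk_air <- locate_defect_peak(g, air, gap = 3)
  expect_equal(pk_air$f_R, 1887.59, tolerance = 0.05 / 1887.59)
  expect_gt(pk_air$T_peak, 99)

  pk_deb <- locate_defect_peak(g, deb0, gap = 3)
  expect_equal(pk_deb$f_R, 1862.89, tolerance = 0.05 / 1862.89)

  # the peak frequency tracks the sound speed exactly (standing-wave scaling)
  expect_equal(pk_air$f_R / pk_deb$f_R,
               air$sound_speed / mixture_sound_speed(deb0),
               tolerance = 1e-3)
})

test_that("no-peak conditions are signalled as errors", {
  # with dd = d1 and a short mirror no mode is pulled into the third gap
  g <- small_geometry(n_cells = 3)
  g$dd <- g$d1
  expect_error(locate_defect_peak(g, air, gap = c(1716, 2008)),
               "no defect peak")
  expect_error(locate_defect_peak(initial_geometry(), air, gap = 99),
               "out of range")
  expect_error(locate_defect_peak(initial_geometry(), air),
               "'gap' or 'f_window'")
})

test_that("peak refinement is stable against the coarse scan step", {
  g <- initial_geometry()
  p1 <- locate_defect_peak(g, air, gap = 3, scan_step = 0.05)
  p2 <- locate_defect_peak(g, air, gap = 3, scan_step = 0.02)
  expect_equal(p1$f_R, p2$f_R, tolerance = 1e-5 / p1$f_R)
})

test_that("half-maximum crossings bracket the peak and shrink with mirror size", {
  widths <- vapply(c(3, 4, 5), function(n) {
    g <- small_geometry(n_cells = n)
    pk <- locate_defect_peak(g, air, gap = c(1716, 2008))
    # crossings bracket f_R
    half <- pk$T_peak / 2
    expect_lt(transmittance(pk$f_R - pk$fwhm, g, air), half)
    expect_lt(transmittance(pk$f_R + pk$fwhm, g, air), half)
    expect_gt(transmittance(pk$f_R, g, air), half)
    pk$fwhm
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("fwhm() and peak_fwhm() agree on a located peak", {
  g <- small_geometry(n_cells = 4)
  pk <- locate_defect_peak(g, air, gap = c(1716, 2008))
  expect_equal(fwhm(g, air, pk), pk$fwhm, tolerance = 1e-6)
})

test_that("standing-wave predictor follows its closed form", {
  expect_equal(standing_wave_frequency(1, 1, 340), 170)
  expect_equal(standing_wave_frequency(1, 4, 340),
               2 * standing_wave_frequency(1, 2, 340))
  expect_error(standing_wave_frequency(1, 1.5, 340))
})

test_that("scalar indicators are the printed ratios with guarded domains", {
  expect_equal(figure_of_merit(5.3, 0.0005), 10600)
  expect_equal(quality_factor(1800, 0.0005), 3.6e6)
  expect_equal(detection_limit(1800, 5.3, 3.6e6), 1800 / (20 * 5.3 * 3.6e6))
  expect_equal(signal_to_noise(0.0005, 0.0005), 1)
  # RS shrinks with linewidth at fixed SNR
  expect_lt(resolution_rs(0.0005, 10), resolution_rs(0.005, 10))
  expect_error(figure_of_merit(-1, 1))
  expect_error(quality_factor(1, 0))
})

test_that("the metrics report satisfies the defining identities exactly", {
  g <- small_geometry(n_cells = 5)
  met <- sensor_metrics(g, deb_mixture(0), deb_mixture(100),
                        f_window = c(1716, 2008))
  expect_equal(met$FoM * met$fwhm, met$S, tolerance = 1e-12)
  expect_equal(met$Q * met$fwhm, met$f_R, tolerance = 1e-12)
  expect_equal(met$LoD * 20 * met$S * met$Q, met$f_R, tolerance = 1e-12)
  expect_equal(met$SNR, met$delta_f / met$fwhm, tolerance = 1e-12)
  expect_equal(met$RS, 2 * met$fwhm / (3 * met$SNR^0.25), tolerance = 1e-12)
  expect_equal(met$S, met$delta_f / met$delta_c, tolerance = 1e-12)

  # the sensitivity approximates the standing-wave proportionality f_R / c
  expect_equal(met$S, met$f_R / mixture_sound_speed(deb_mixture(0)),
               tolerance = 0.02)
})

test_that("sensitivity demands distinct sound speeds", {
  g <- small_geometry()
  expect_error(sensitivity(g, deb_mixture(0), deb_mixture(0),
                           gap = c(1716, 2008)),
               "identical sound speeds")
})

test_that("red shift under enrichment is monotone with near-uniform steps", {
  g <- initial_geometry()
  units <- seq(0, 100, by = 20)
  f_r <- vapply(units, function(u) {
    locate_defect_peak(g, deb_mixture(u), gap = 3)$f_R
  }, numeric(1))
  steps <- -diff(f_r)
  expect_true(all(steps > 0))
  expect_true(all(abs(steps - mean(steps)) / mean(steps) < 0.05))
})

test_that("calibration fit recovers exact and computed lines", {
  # perfectly linear synthetic input: zero residual, exact slope
  cal <- calibration_fit(c(0, 25, 50, 75, 100),
                         f_R_values = 1800 - 0.06 * c(0, 25, 50, 75, 100))
  expect_equal(cal$slope, -0.06, tolerance = 1e-12)
  expect_equal(cal$rss, 0, tolerance = 1e-18)
  expect_equal(unname(coef(cal)), c(1800, -0.06), tolerance = 1e-12)
  expect_equal(predict(cal, 10), c(`1` = 1799.4), tolerance = 1e-12)
  expect_error(calibration_fit(c(0, 0, 0), f_R_values = c(1, 2, 3)),
               "3 distinct")

  # computed peaks: a 3-level fit matches the 6-level fit within 1%
  g <- small_geometry(n_cells = 5)
  cal6 <- calibration_fit(seq(0, 100, 20), geometry = g,
                          f_window = c(1716, 2008))
  cal3 <- calibration_fit(c(0, 50, 100), geometry = g,
                          f_window = c(1716, 2008))
  expect_lt(cal6$slope, 0)
  expect_equal(cal3$slope, cal6$slope, tolerance = 0.01)
  expect_gt(cal6$r_squared, 0.999)
})
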