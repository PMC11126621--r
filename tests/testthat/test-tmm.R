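test_that("duct impedance is rho*c/S with reciprocal admittance", {
  z <- duct_impedance(air, 1e-4)
  expect_equal(z, 1.2047 * 343 / 1e-4)
  expect_equal(duct_impedance(air, 2e-4), z / 2)
  expect_error(duct_impedance(air, 0), "positive")
})

test_that("branch admittances match their closed forms and special points", {
  g <- sensor_geometry(d1 = 10, d2 = 5, d3 = 8, dd = 33,
                       S1 = 1, S2 = 0.9, S3 = 0.9, Sd = 1, units = "cm")
  c0 <- air$sound_speed

  # open branch: k*d3 = pi/2  =>  cot = 0
  f_quarter <- c0 / (4 * g$d3)
  expect_equal(Mod(open_branch_admittance(f_quarter, g, air)), 0,
               tolerance = 1e-9)
  # open stub shorts the duct at low frequency: |y_O| grows like 1/f
  expect_equal(Mod(open_branch_admittance(1e-6, g, air)) /
                 Mod(open_branch_admittance(1e-4, g, air)), 100,
               tolerance = 1e-6)

  # closed branch: tan(0) = 0 at low frequency; k*d2 = pi/4 => y = j/Z2
  expect_equal(Mod(closed_branch_admittance(1e-6, g, air)), 0,
               tolerance = 1e-12)
  f_eighth <- c0 / (8 * g$d2)
  Z2 <- duct_impedance(air, g$S2)
  expect_equal(closed_branch_admittance(f_eighth, g, air), 1i / Z2,
               tolerance = 1e-9)

  # generic frequencies: direct evaluation, purely imaginary, additive
  for (f in c(123.4, 987.6, 1771.1)) {
    k <- 2 * pi * f / c0
    y_o <- -1i / (duct_impedance(air, g$S3) * tan(k * g$d3))
    y_c <- 1i * tan(k * g$d2) / duct_impedance(air, g$S2)
    expect_equal(open_branch_admittance(f, g, air), y_o)
    expect_equal(closed_branch_admittance(f, g, air), y_c)
    expect_equal(combined_admittance(f, g, air), y_o + y_c)
    expect_equal(Re(combined_admittance(f, g, air)), 0)
  }
})

test_that("cell, defect and assembled matrices are unimodular across the band", {
  g <- small_geometry()
  dets <- function(m) Mod(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1] - 1)
  for (f in c(0.1, 17, 333.3, 1887.59, 2999, 5000)) {
    expect_lt(dets(unit_cell_matrix(f, g, air)), 1e-9)
    expect_lt(dets(defect_cell_matrix(f, g, air)), 1e-9)
    expect_lt(dets(assemble_total_matrix(f, g, air)), 1e-9)
  }
})

test_that("unit cell collapses to a plain duct when the shunt load vanishes", {
  # with d2 = d3 and S2 = S3 the two branch admittances cancel at k*d2 = pi/4
  g <- small_geometry()
  f0 <- air$sound_speed / (8 * g$d2)
  expect_equal(Mod(combined_admittance(f0, g, air)), 0, tolerance = 1e-12)
  expect_equal(unit_cell_matrix(f0, g, air),
               duct_matrix(f0, g$d1, air, g$S1), tolerance = 1e-12)
})

test_that("defect matrix is the full-length guide with the expected limits", {
  g <- small_geometry()
  # quarter-wave argument of the half-length factor: k*dd/2 = pi/2
  f_q <- air$sound_speed / (2 * g$dd)
  half <- duct_matrix(f_q, g$dd / 2, air, g$Sd)
  Zd <- duct_impedance(air, g$Sd)
  expect_equal(half[1, 1], 0 + 0i, tolerance = 1e-9)
  expect_equal(half[2, 2], 0 + 0i, tolerance = 1e-9)
  expect_equal(half[1, 2], 1i * Zd, tolerance = 1e-9)
  expect_equal(half[2, 1], 1i / Zd, tolerance = 1e-9)
  expect_equal(defect_cell_matrix(f_q, g, air), half %*% half)

  # vanishing guide length -> identity
  g0 <- g
  g0$dd <- 1e-16
  expect_equal(defect_cell_matrix(100, g0, air), diag(2) + 0i,
               tolerance = 1e-6)

  # generic frequency: entries from the trigonometric definitions
  f <- 771.3
  k <- 2 * pi * f / air$sound_speed
  m <- defect_cell_matrix(f, g, air)
  expect_equal(m[1, 1], cos(k * g$dd) + 0i, tolerance = 1e-12)
  expect_equal(m[1, 2], 1i * Zd * sin(k * g$dd), tolerance = 1e-12)
})

test_that("assembled chain equals the explicit matrix product", {
  g <- small_geometry(n_cells = 2)
  for (f in c(451.7, 1887.59)) {
    u <- unit_cell_matrix(f, g, air)
    d <- defect_cell_matrix(f, g, air)
    expect_equal(assemble_total_matrix(f, g, air), u %*% u %*% d %*% u %*% u,
                 tolerance = 1e-12)
    expect_equal(assemble_total_matrix(f, g, air, include_defect = FALSE),
                 u %*% u %*% u %*% u, tolerance = 1e-12)
  }
})

test_that("vectorised transmittance agrees with the brute-force matrix route", {
  g <- small_geometry(n_cells = 4)
  f <- c(50, 313.7, 900, 1500.2, 1887.59, 2750)
  t_vec <- transmittance(f, g, air)
  t_brute <- vapply(f, oracle_transmittance, numeric(1), g = g, medium = air)
  expect_equal(t_vec, t_brute, tolerance = 1e-9)
  t_vec_nd <- transmittance(f, g, air, include_defect = FALSE)
  t_brute_nd <- vapply(f, oracle_transmittance, numeric(1), g = g,
                       medium = air, include_defect = FALSE)
  expect_equal(t_vec_nd, t_brute_nd, tolerance = 1e-9)
})

test_that("a matched uniform line transmits fully", {
  g <- small_geometry()
  # at the shunt-cancellation frequency every element is a matched S1 duct
  f0 <- air$sound_speed / (8 * g$d2)
  expect_equal(transmittance(f0, g, air), 100, tolerance = 1e-9)

  # with negligible branch cross-sections the whole spectrum is flat
  g_bare <- sensor_geometry(d1 = 0.1, d2 = 0.06, d3 = 0.06, dd = 0.33,
                            S1 = 1e-4, S2 = 1e-16, S3 = 1e-16, Sd = 1e-4)
  sp <- transmittance_spectrum(g_bare, air, f_start = 10, f_stop = 2000,
                               step = 10)
  expect_true(all(abs(sp$transmittance - 100) < 1e-4))
})

test_that("transmittance respects the lossless energy bound", {
  g <- initial_geometry()
  set.seed(11)
  f <- sort(runif(400, 0.1, 5000))
  tt <- transmittance(f, g, air)
  expect_true(all(tt >= 0))
  expect_true(all(tt <= 100 + 1e-6))
})

test_that("open-branch poles short the duct (T -> 0), without NaNs", {
  g <- initial_geometry()
  f_pole <- air$sound_speed / (2 * g$d3) # sin(k d3) = 0
  tt <- transmittance(c(f_pole, f_pole * 2), g, air)
  expect_true(all(is.finite(tt)))
  expect_true(all(tt < 1e-3))
})

test_that("uniform density scaling leaves the spectrum unchanged", {
  g <- initial_geometry()
  f <- seq(100, 2800, by = 37)
  base <- transmittance(f, g, air)
  for (lambda in c(0.2, 5, 40)) {
    scaled <- transmittance(f, g, acoustic_medium(343, 1.2047 * lambda))
    expect_equal(scaled, base, tolerance = 1e-9)
  }
})

test_that("midgap leakage of the defect-free crystal decays with mirror size", {
  mid <- 1860 # inside the third gap of the initial design
  t_n <- vapply(c(2, 3, 4, 5), function(n) {
    transmittance(mid, small_geometry(n_cells = n), air,
                  include_defect = FALSE)
  }, numeric(1))
  expect_true(all(diff(t_n) < 0))
})

test_that("spectra are ordered, deterministic and refinement-stable", {
  g <- initial_geometry()
  sp <- transmittance_spectrum(g, air, f_start = 1800, f_stop = 1950,
                               step = 0.5)
  expect_s3_class(sp, "pnc_spectrum")
  expect_true(all(diff(sp$frequency) > 0))
  sp2 <- transmittance_spectrum(g, air, f_start = 1800, f_stop = 1950,
                                step = 0.5)
  expect_identical(sp, sp2)
  # peak position is stable under grid refinement
  fine <- transmittance_spectrum(g, air, f_start = 1885, f_stop = 1890,
                                 step = 0.01)
  finer <- transmittance_spectrum(g, air, f_start = 1885, f_stop = 1890,
                                  step = 0.005)
  expect_equal(fine$frequency[which.max(fine$transmittance)],
               finer$frequency[which.max(finer$transmittance)],
               tolerance = 0.02)
})
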