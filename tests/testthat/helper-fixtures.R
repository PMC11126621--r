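# Shared fixtures and an independent brute-force route for cross-checks.

air <- acoustic_medium(343, 1.2047)
deb0 <- deb_mixture(0)

# small mirror for cheap property tests
small_geometry <- function(n_cells = 3) {
  sensor_geometry(d1 = 10, d2 = 6, d3 = 6, dd = 33,
                  S1 = 1, S2 = 0.9, S3 = 0.9, Sd = 1,
                  n_cells = n_cells, units = "cm")
}

# Independent transmittance oracle: explicit 2x2 matrices multiplied with %*%,
# built directly from the duct/shunt definitions (no package kernel involved).
oracle_transmittance <- function(f, g, medium, include_defect = TRUE) {
  c0 <- medium$sound_speed
  rho <- medium$density
  k <- 2 * pi * f / c0
  dm <- function(L, S) {
    Z <- rho * c0 / S
    matrix(c(cos(k * L), 1i * sin(k * L) / Z,
             1i * Z * sin(k * L), cos(k * L)), 2, 2)
  }
  y <- 1i * tan(k * g$d2) * g$S2 / (rho * c0) -
    1i * g$S3 / (rho * c0 * tan(k * g$d3))
  cell <- dm(g$d1 / 2, g$S1) %*% matrix(c(1, y, 0, 1), 2, 2) %*%
    dm(g$d1 / 2, g$S1)
  side <- Reduce(`%*%`, rep(list(cell), g$n_cells))
  total <- if (include_defect) side %*% dm(g$dd, g$Sd) %*% side else
    side %*% side
  Y1 <- g$S1 / (rho * c0)
  t <- 2 * Y1 / ((total[1, 1] + total[1, 2] * Y1) * Y1 +
                   total[2, 1] + total[2, 2] * Y1)
  100 * Mod(t)^2
}
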