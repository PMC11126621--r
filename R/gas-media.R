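# Gas species, mixtures and effective acoustic media.
#
# Dry exhaled breath (DEB) is modelled as an ideal mixture of N2, O2, CO2 and
# Ar.  The effective sound speed of a mixture is the density-weighted mean of
# the component speeds,
#
#     c_mix = sum(a_i * rho_i * c_i) / sum(a_i * rho_i),
#
# and the effective density is the volume-fraction-weighted sum
#
#     rho_mix = sum(a_i * rho_i),
#
# where a_i are volume fractions.  Temperature gradients, humidity and real-gas
# corrections are out of scope: the sample is assumed dry, stationary and at
# room temperature.

#' Create a gas species
#'
#' @param name Species identifier, e.g. `"CO2"`.
#' @param density Mass density in kg/m^3; must be positive.
#' @param sound_speed Speed of sound in m/s; must be positive.
#'
#' @return An object of class `gas_species`.
#' @examples
#' gas_species("He", 0.1664, 1007)
#' @export
gas_species <- function(name, density, sound_speed) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    stop("'density' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(sound_speed) || length(sound_speed) != 1L ||
      !is.finite(sound_speed) || sound_speed <= 0) {
    stop("'sound_speed' must be a single positive number", call. = FALSE)
  }
  structure(
    list(name = name, density = density, sound_speed = sound_speed),
    class = "gas_species"
  )
}

#' @export
print.gas_species <- function(x, ...) {
  cat(sprintf("<gas_species> %s: rho = %g kg/m^3, c = %g m/s\n",
              x$name, x$density, x$sound_speed))
  invisible(x)
}

#' Built-in pure-gas acoustic constants
#'
#' Room-temperature mass densities (kg/m^3) and sound speeds (m/s) of the pure
#' gases relevant to dry exhaled breath, plus air.
#'
#' @return A named list of [gas_species] objects with entries
#'   `CO2`, `Ar`, `O2`, `Air` and `N2`.
#' @examples
#' builtin_species()$CO2
#' @export
builtin_species <- function() {
  list(
    CO2 = gas_species("CO2", 1.8393, 267),
    Ar  = gas_species("Ar",  1.661,  319),
    O2  = gas_species("O2",  1.314,  326),
    Air = gas_species("Air", 1.2047, 343),
    N2  = gas_species("N2",  1.165,  349)
  )
}

#' Create a gas mixture from volume fractions
#'
#' @param fractions Named numeric vector of volume fractions.  Names must
#'   resolve in `species`; fractions must be non-negative and sum to 1 within
#'   `1e-12`.
#' @param species Named list of [gas_species] providing the acoustic constants;
#'   defaults to [builtin_species()].  Entries may be overridden or extended.
#'
#' @return An object of class `gas_mixture`: a data frame with columns `name`,
#'   `fraction`, `density` and `sound_speed`.
#' @examples
#' gas_mixture(c(N2 = 0.78, O2 = 0.16, CO2 = 0.05, Ar = 0.01))
#' @export
gas_mixture <- function(fractions, species = builtin_species()) {
  if (length(fractions) == 0L) {
    stop("mixture must contain at least one component", call. = FALSE)
  }
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("'fractions' must be a named numeric vector", call. = FALSE)
  }
  if (any(!is.finite(fractions)) || any(fractions < 0)) {
    stop("volume fractions must be finite and non-negative", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-12) {
    stop(sprintf("volume fractions must sum to 1 (got %.15g)", sum(fractions)),
         call. = FALSE)
  }
  missing <- setdiff(names(fractions), names(species))
  if (length(missing)) {
    stop("unknown species: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  sp <- species[names(fractions)]
  out <- data.frame(
    name        = names(fractions),
    fraction    = as.numeric(fractions),
    density     = vapply(sp, `[[`, numeric(1), "density"),
    sound_speed = vapply(sp, `[[`, numeric(1), "sound_speed"),
    row.names   = NULL,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gas_mixture", "data.frame")
  out
}

#' @export
print.gas_mixture <- function(x, ...) {
  cat("<gas_mixture>\n")
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("effective: c = %.4f m/s, rho = %.6f kg/m^3\n",
              mixture_sound_speed(x), mixture_density(x)))
  invisible(x)
}

#' Effective sound speed of a gas mixture
#'
#' Density-weighted average of the component sound speeds:
#' `sum(a*rho*c) / sum(a*rho)`.
#'
#' @param mix A [gas_mixture].
#' @return Effective sound speed in m/s.
#' @examples
#' mixture_sound_speed(deb_mixture(0)) # normal dry exhaled breath, 338.51 m/s
#' @export
mixture_sound_speed <- function(mix) {
  stopifnot(inherits(mix, "gas_mixture"))
  sum(mix$fraction * mix$density * mix$sound_speed) /
    sum(mix$fraction * mix$density)
}

#' Effective mass density of a gas mixture
#'
#' Volume-fraction-weighted sum of component densities: `sum(a*rho)`.
#'
#' @inheritParams mixture_sound_speed
#' @return Effective density in kg/m^3.
#' @examples
#' mixture_density(deb_mixture(0)) # 1.2275 kg/m^3
#' @export
mixture_density <- function(mix) {
  stopifnot(inherits(mix, "gas_mixture"))
  sum(mix$fraction * mix$density)
}

#' Homogeneous acoustic medium
#'
#' The duct network sees the filling gas only through its sound speed and
#' density; this lightweight container carries both.
#'
#' @param sound_speed Speed of sound in m/s (> 0).
#' @param density Mass density in kg/m^3 (> 0).
#' @return An object of class `acoustic_medium`.
#' @examples
#' acoustic_medium(343, 1.2047)
#' @export
acoustic_medium <- function(sound_speed, density) {
  if (!is.numeric(sound_speed) || length(sound_speed) != 1L ||
      !is.finite(sound_speed) || sound_speed <= 0) {
    stop("'sound_speed' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    stop("'density' must be a single positive number", call. = FALSE)
  }
  structure(list(sound_speed = sound_speed, density = density),
            class = "acoustic_medium")
}

#' @export
print.acoustic_medium <- function(x, ...) {
  cat(sprintf("<acoustic_medium> c = %g m/s, rho = %g kg/m^3\n",
              x$sound_speed, x$density))
  invisible(x)
}

#' Effective acoustic medium of a mixture, species or medium
#'
#' @param x A [gas_mixture], [gas_species] or [acoustic_medium].
#' @return An [acoustic_medium].
#' @export
effective_medium <- function(x) {
  if (inherits(x, "acoustic_medium")) return(x)
  if (inherits(x, "gas_species")) {
    return(acoustic_medium(x$sound_speed, x$density))
  }
  if (inherits(x, "gas_mixture")) {
    return(acoustic_medium(mixture_sound_speed(x), mixture_density(x)))
  }
  stop("cannot interpret 'x' as an acoustic medium", call. = FALSE)
}

#' Air as an acoustic medium
#'
#' @return An [acoustic_medium] with the built-in constants for air.
#' @export
air_medium <- function() {
  effective_medium(builtin_species()$Air)
}

#' Dry exhaled breath with CO2 enrichment
#'
#' Normal dry exhaled breath (DEB) is N2 78%, O2 16%, CO2 5% and Ar 1% by
#' volume.  One enrichment unit raises the CO2 volume fraction by 0.01
#' percentage point (so 100 units take CO2 from 5% to 6%); the remaining gases
#' are rescaled proportionally (ratios 78:16:1 preserved) so the fractions
#' still sum to one.
#'
#' @param enrichment_units CO2 enrichment above the normal ratio, in units of
#'   0.01 percentage point of volume fraction.  The studied range is 0-100; a
#'   warning is issued outside it.
#' @param species Species table, see [gas_mixture()].
#' @return A [gas_mixture].
#' @examples
#' deb_mixture(0)    # normal breath
#' deb_mixture(100)  # CO2 at 6%
#' @export
deb_mixture <- function(enrichment_units = 0, species = builtin_species()) {
  stopifnot(is.numeric(enrichment_units), length(enrichment_units) == 1L,
            is.finite(enrichment_units))
  if (enrichment_units < 0 || enrichment_units > 100) {
    warning("enrichment_units outside the studied range [0, 100]",
            call. = FALSE)
  }
  co2 <- 0.05 + enrichment_units * 1e-4
  if (co2 >= 1) {
    stop("enrichment pushes the CO2 fraction to 1 or above", call. = FALSE)
  }
  if (co2 < 0) {
    stop("enrichment pushes the CO2 fraction below 0", call. = FALSE)
  }
  rest <- c(N2 = 0.78, O2 = 0.16, Ar = 0.01)
  rest <- rest / sum(rest) * (1 - co2)
  gas_mixture(c(rest, CO2 = co2), species = species)
}

#' Tabulate a mixture as delimited text
#'
#' Writes one row per component: `name`, `fraction`, `density`, `sound_speed`,
#' followed by the effective constants as comment lines.
#'
#' @param mix A [gas_mixture].
#' @param path File path, or `""` for standard output.
#' @return Invisibly, the mixture.
#' @export
write_mixture <- function(mix, path = "") {
  stopifnot(inherits(mix, "gas_mixture"))
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  writeLines(sprintf("# effective_sound_speed_m_s: %.6f",
                     mixture_sound_speed(mix)), con)
  writeLines(sprintf("# effective_density_kg_m3: %.6f",
                     mixture_density(mix)), con)
  utils::write.table(mix, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mix)
}
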