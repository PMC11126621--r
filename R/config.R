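# Structured (YAML) configuration: geometry + mixture + scan + peak-search
# blocks.  Paper-style units (cm, cm^2) are accepted on ingest and normalised
# to SI.

#' Named reference configurations
#'
#' `initial` is the starting design (see [initial_geometry()]) operating on
#' the third band gap; `optimized` differs in exactly two fields (`d1` 10 -> 20
#' cm, `dd` 33 -> 100 cm) and carries the operating frequency window of the
#' tracked defect mode.  Both pair normal dry exhaled breath (enrichment 0)
#' with the fully enriched mixture (100 units, CO2 6%).
#'
#' @return A named list of configuration lists suitable for
#'   [write_sensor_config()] / [resolve_sensor_config()].
#' @examples
#' names(fixture_configs())
#' @export
fixture_configs <- function() {
  initial <- list(
    geometry = list(units = "cm", d1 = 10, d2 = 6, d3 = 6, dd = 33,
                    S1 = 1, S2 = 0.9, S3 = 0.9, Sd = 1, n_cells = 10),
    mixture = list(deb_enrichment = 0),
    mixture_high = list(deb_enrichment = 100),
    scan = list(f_start = 0.1, f_stop = 3000, step = 0.05),
    peak = list(gap_index = 3, threshold = 1)
  )
  optimized <- initial
  optimized$geometry$d1 <- 20
  optimized$geometry$dd <- 100
  optimized$peak <- list(f_window = c(1700, 1910), threshold = 1)
  list(initial = initial, optimized = optimized)
}

# resolve a mixture block: named fractions, {air: true}, or
# {deb_enrichment: units}
.resolve_mixture <- function(block, species) {
  if (is.null(block)) return(NULL)
  if (isTRUE(block$air)) return(builtin_species()$Air)
  if (!is.null(block$deb_enrichment)) {
    return(deb_mixture(block$deb_enrichment, species = species))
  }
  if (!is.null(block$sound_speed) && !is.null(block$density)) {
    return(acoustic_medium(block$sound_speed, block$density))
  }
  gas_mixture(unlist(block), species = species)
}

#' Resolve a raw configuration list
#'
#' Validates and converts a configuration (as read from YAML) into package
#' objects: the geometry in SI units, the mixture pair, and the scan and
#' peak-search settings.
#'
#' @param cfg A configuration list with blocks `geometry` (required; fields of
#'   [sensor_geometry()] plus `units`), `mixture` / `mixture_high` (named
#'   volume fractions, `{air: true}`, `{deb_enrichment: u}` or explicit
#'   `{sound_speed, density}`), optional `species` overrides (name ->
#'   `{density, sound_speed}`), `scan` (`f_start`, `f_stop`, `step`) and
#'   `peak` (`gap_index` or `f_window`, `threshold`).
#' @return A list of class `sensor_config` with elements `geometry`,
#'   `mixture`, `mixture_high`, `scan`, `peak` and `raw`.
#' @export
resolve_sensor_config <- function(cfg) {
  if (is.null(cfg$geometry)) stop("config lacks a 'geometry' block",
                                  call. = FALSE)
  gb <- cfg$geometry
  units <- if (is.null(gb$units)) "m" else gb$units
  geometry <- sensor_geometry(
    d1 = gb$d1, d2 = gb$d2, d3 = gb$d3, dd = gb$dd,
    S1 = gb$S1, S2 = gb$S2, S3 = gb$S3, Sd = gb$Sd,
    n_cells = if (is.null(gb$n_cells)) 10 else gb$n_cells,
    units = units
  )
  species <- builtin_species()
  for (nm in names(cfg$species)) {
    species[[nm]] <- gas_species(nm, cfg$species[[nm]]$density,
                                 cfg$species[[nm]]$sound_speed)
  }
  mixture <- .resolve_mixture(cfg$mixture, species)
  if (is.null(mixture)) mixture <- deb_mixture(0, species = species)
  mixture_high <- .resolve_mixture(cfg$mixture_high, species)
  if (is.null(mixture_high)) mixture_high <- deb_mixture(100, species = species)
  scan <- utils::modifyList(list(f_start = 0.1, f_stop = 3000, step = 0.05),
                            as.list(cfg$scan))
  peak <- utils::modifyList(list(threshold = 1), as.list(cfg$peak))
  if (is.null(peak$gap_index) && is.null(peak$f_window)) peak$gap_index <- 3
  structure(
    list(geometry = geometry, mixture = mixture, mixture_high = mixture_high,
         scan = scan, peak = peak, raw = cfg),
    class = "sensor_config"
  )
}

#' Read / write sensor configurations (YAML)
#'
#' @param path Path to a YAML configuration file.
#' @return `read_sensor_config()` returns a resolved `sensor_config` (see
#'   [resolve_sensor_config()]); `write_sensor_config()` returns the path,
#'   invisibly.
#' @export
read_sensor_config <- function(path) {
  resolve_sensor_config(yaml::read_yaml(path))
}

#' @rdname read_sensor_config
#' @param cfg A raw configuration list (e.g. one entry of
#'   [fixture_configs()]).
#' @export
write_sensor_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# peak-search arguments from a resolved config
.peak_args <- function(config) {
  p <- config$peak
  if (!is.null(p$f_window)) {
    list(f_window = as.numeric(p$f_window), threshold = p$threshold,
         f_stop = config$scan$f_stop)
  } else {
    list(gap = p$gap_index, threshold = p$threshold,
         f_stop = config$scan$f_stop)
  }
}

# resolved SI parameters for output headers
.config_header <- function(config) {
  g <- config$geometry
  m <- effective_medium(config$mixture)
  list(
    tool = paste0("pncsense ",
                  as.character(utils::packageVersion("pncsense"))),
    d1_m = g$d1, d2_m = g$d2, d3_m = g$d3, dd_m = g$dd,
    S1_m2 = g$S1, S2_m2 = g$S2, S3_m2 = g$S3, Sd_m2 = g$Sd,
    n_cells_per_side = g$n_cells,
    sound_speed_m_s = m$sound_speed, density_kg_m3 = m$density
  )
}
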