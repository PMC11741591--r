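AVOGADRO <- 6.02214076e23  # 1/mol (CODATA)
LITRES_PER_UM3 <- 1e-15

#' Soma geometry for count/concentration conversions
#'
#' The model treats the neuronal soma as one well-mixed compartment of fixed
#' volume; a sphere of the same volume supplies the surface area used to
#' convert receptor surface densities into receptor counts.
#'
#' @param volume_um3 Soma volume in cubic micrometres (default 4850, the
#'   common value assumed for both neuron groups).
#'
#' @return An object of class `soma_geometry` with fields `volume_um3`,
#'   `radius_um` and `area_um2`.
#' @examples
#' soma_geometry()          # 4850 um^3 sphere
#' soma_geometry(12000)
#' @export
soma_geometry <- function(volume_um3 = 4850) {
  if (!is.numeric(volume_um3) || length(volume_um3) != 1L ||
      !is.finite(volume_um3) || volume_um3 <= 0) {
    stop("soma volume must be a single positive number (um^3)", call. = FALSE)
  }
  radius <- (3 * volume_um3 / (4 * pi))^(1 / 3)
  structure(
    list(volume_um3 = volume_um3, radius_um = radius,
         area_um2 = 4 * pi * radius^2),
    class = "soma_geometry"
  )
}

#' @export
print.soma_geometry <- function(x, ...) {
  cat(sprintf("soma: volume %g um^3, sphere radius %.3f um, area %.1f um^2\n",
              x$volume_um3, x$radius_um, x$area_um2))
  invisible(x)
}

#' Convert molecule counts to molar concentration
#'
#' @param count Molecule count(s), >= 0.
#' @param geometry A [soma_geometry()].
#' @return Concentration in mol/L.
#' @examples
#' molecules_to_molar(2.9207e5, soma_geometry())  # ~1e-7 M (100 nM)
#' @export
molecules_to_molar <- function(count, geometry = soma_geometry()) {
  stopifnot(inherits(geometry, "soma_geometry"))
  if (any(!is.finite(count)) || any(count < 0)) {
    stop("count must be finite and non-negative", call. = FALSE)
  }
  count / (AVOGADRO * geometry$volume_um3 * LITRES_PER_UM3)
}

#' Convert molar concentration to molecule counts
#'
#' Exact inverse of [molecules_to_molar()]; no rounding is applied, so
#' fractional molecule counts are returned as-is.
#'
#' @param conc Concentration(s) in mol/L, >= 0.
#' @param geometry A [soma_geometry()].
#' @return Molecule count (possibly fractional).
#' @examples
#' molar_to_molecules(100e-9, soma_geometry())  # ~292070 molecules
#' @export
molar_to_molecules <- function(conc, geometry = soma_geometry()) {
  stopifnot(inherits(geometry, "soma_geometry"))
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentration must be finite and non-negative", call. = FALSE)
  }
  conc * AVOGADRO * geometry$volume_um3 * LITRES_PER_UM3
}

#' First-order rate constant from a half-life
#'
#' Returns `log(2) / t_half`. Note that the canonical parameter table rounds
#' these conversions (6.9 h -> 0.1005 -> 0.1; 15 h -> 0.0462 -> 0.05;
#' 35 h -> 0.0198 -> 0.02; ~1 h -> 0.693 -> 0.65): the printed table values,
#' not this helper's output, parameterize the built-in neuron profiles.
#'
#' @param t_half Half-life in hours, > 0.
#' @return Rate constant in 1/h.
#' @examples
#' rate_from_half_life(6.9)   # 0.1005 (table uses 0.1)
#' rate_from_half_life(35)    # 0.0198 (table uses 0.02)
#' @export
rate_from_half_life <- function(t_half) {
  if (any(!is.finite(t_half)) || any(t_half <= 0)) {
    stop("half-life must be finite and positive", call. = FALSE)
  }
  log(2) / t_half
}

#' Receptor count from a surface density
#'
#' Multiplies an area density (molecules per square micrometre) by the sphere
#' surface area of the soma. A density of 36 /um^2 on the default 4850 um^3
#' soma gives ~5e4 receptors; 180 /um^2 gives ~2.5e5.
#'
#' @param density Surface density, molecules per um^2, >= 0.
#' @param geometry A [soma_geometry()].
#' @return Receptor count (molecules).
#' @examples
#' receptors_from_surface_density(36)   # ~50000
#' receptors_from_surface_density(180)  # ~250000
#' @export
receptors_from_surface_density <- function(density, geometry = soma_geometry()) {
  stopifnot(inherits(geometry, "soma_geometry"))
  if (any(!is.finite(density)) || any(density < 0)) {
    stop("density must be finite and non-negative", call. = FALSE)
  }
  density * geometry$area_um2
}
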