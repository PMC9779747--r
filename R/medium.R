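# Physical constants and the Stokes-Einstein machinery shared by the
# nanotracking and light-scattering stages.

# Boltzmann constant, J/K (exact, 2019 SI).
.kB <- 1.380649e-23

#' Medium conditions for diffusion and scattering calculations
#'
#' Bundles the solvent properties that enter the Stokes-Einstein relation
#' (temperature, viscosity) and the scattering vector (refractive index).
#' Defaults describe water at 25 degrees Celsius.
#'
#' @param temperature Absolute temperature in kelvin.
#' @param viscosity Dynamic viscosity in pascal-seconds. The default
#'   8.9e-4 Pa s is the handbook value for water at 25 C.
#' @param refractive_index Refractive index of the medium (dimensionless),
#'   1.33 for water in the visible range.
#'
#' @return An object of class `scp_medium`.
#' @examples
#' medium_conditions()
#' medium_conditions(temperature = 310.15)  # body temperature
#' @export
medium_conditions <- function(temperature = 298.15,
                              viscosity = 8.9e-4,
                              refractive_index = 1.33) {
  for (v in c(temperature, viscosity, refractive_index)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("medium fields must be single, finite, strictly positive numbers",
           call. = FALSE)
    }
  }
  structure(
    list(temperature = temperature,
         viscosity = viscosity,
         refractive_index = refractive_index),
    class = "scp_medium"
  )
}

#' @export
print.scp_medium <- function(x, ...) {
  cat(sprintf("<medium> T = %.2f K, eta = %.3g Pa s, n0 = %.3f\n",
              x$temperature, x$viscosity, x$refractive_index))
  invisible(x)
}

.check_medium <- function(medium) {
  if (!inherits(medium, "scp_medium")) {
    stop("`medium` must be created by medium_conditions()", call. = FALSE)
  }
  medium
}

#' Diffusion coefficient of a sphere (Stokes-Einstein)
#'
#' Translational diffusion coefficient of a sphere of hydrodynamic radius
#' `rh` in a medium of viscosity eta at temperature T:
#' D = kT / (6 pi eta Rh).
#'
#' @param rh Hydrodynamic radius in meters (vectorized).
#' @param medium A [medium_conditions()] object.
#'
#' @return Diffusion coefficient(s) in m^2/s.
#' @examples
#' diffusion_coefficient_sphere(100e-9)  # ~2.45e-12 m^2/s in water at 25 C
#' @export
diffusion_coefficient_sphere <- function(rh, medium = medium_conditions()) {
  .check_medium(medium)
  if (!is.numeric(rh) || any(!is.finite(rh)) || any(rh <= 0)) {
    stop("`rh` must be finite and strictly positive", call. = FALSE)
  }
  .kB * medium$temperature / (6 * pi * medium$viscosity * rh)
}

#' Hydrodynamic radius from a diffusion coefficient
#'
#' Inverts the Stokes-Einstein relation: Rh = kT / (6 pi eta D).
#'
#' @param D Diffusion coefficient in m^2/s (vectorized).
#' @param medium A [medium_conditions()] object.
#'
#' @return Hydrodynamic radius in meters.
#' @examples
#' rh_from_diffusion(diffusion_coefficient_sphere(100e-9))  # 1e-7 m
#' @export
rh_from_diffusion <- function(D, medium = medium_conditions()) {
  .check_medium(medium)
  if (!is.numeric(D) || any(!is.finite(D)) || any(D <= 0)) {
    stop("`D` must be finite and strictly positive", call. = FALSE)
  }
  .kB * medium$temperature / (6 * pi * medium$viscosity * D)
}

#' Translational diffusion coefficient of a rigid rod
#'
#' Orientation-averaged translational diffusion coefficient of a rigid
#' cylinder of length L and diameter d, using the slender-body expression of
#' Tirado and Garcia de la Torre with end-effect correction:
#' D = kT (ln p + nu) / (3 pi eta L), with aspect ratio p = L/d and
#' nu = 0.312 + 0.565/p + 0.100/p^2.
#'
#' Non-globular particles (e.g. rod-like scale complexes shed from algal
#' flagella) diffuse with this D; feeding it through the sphere-based
#' Stokes-Einstein inversion yields an "equivalent sphere" radius that is
#' a biased summary of the true geometry.
#'
#' @param length Rod length in meters.
#' @param diameter Rod diameter in meters; must be smaller than `length`.
#' @param medium A [medium_conditions()] object.
#'
#' @return Diffusion coefficient in m^2/s. Always lies between the sphere
#'   values at radii `length/2` and `diameter/2`.
#' @examples
#' diffusion_coefficient_rod(400e-9, 20e-9)
#' @export
diffusion_coefficient_rod <- function(length, diameter,
                                      medium = medium_conditions()) {
  .check_medium(medium)
  if (!is.numeric(length) || !is.numeric(diameter) ||
      any(!is.finite(length)) || any(!is.finite(diameter)) ||
      any(diameter <= 0)) {
    stop("rod dimensions must be finite and positive", call. = FALSE)
  }
  if (any(length <= diameter)) {
    stop("rod aspect ratio must exceed 1 (length > diameter)", call. = FALSE)
  }
  p <- length / diameter
  nu <- 0.312 + 0.565 / p + 0.100 / p^2
  .kB * medium$temperature * (log(p) + nu) /
    (3 * pi * medium$viscosity * length)
}
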