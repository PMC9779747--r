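# Particle-population and acquisition descriptors consumed by the synthetic
# generators and, for acquisition metadata, carried along with track sets.

#' Spherical particle population
#'
#' Describes one monodisperse spherical population by its hydrodynamic
#' radius and number density. Setting `alpha < 1` makes the population
#' subdiffusive: its two-dimensional mean squared displacement follows
#' MSD(dt) = 4 K dt^alpha instead of 4 D dt, emulating obstruction by a
#' filament network. `K` (units m^2 s^-alpha) is only used when
#' `alpha < 1`; if omitted it is chosen so that the lag-`match_lag` MSD
#' matches that of free diffusion at radius `rh` (see
#' [simulate_tracks()]).
#'
#' @param rh Hydrodynamic radius in meters.
#' @param number_density Stock number density in particles per mL (before
#'   any dilution applied at acquisition time).
#' @param alpha Anomalous-diffusion exponent in (0, 1]; 1 is ordinary
#'   Brownian motion.
#' @param K Generalized diffusion coefficient, m^2 s^-alpha; `NULL` to
#'   derive from `rh` at simulation time.
#'
#' @return An object of class `scp_population`.
#' @examples
#' sphere_population(100e-9, 2e10)
#' sphere_population(100e-9, 2e10, alpha = 0.7)
#' @export
sphere_population <- function(rh, number_density, alpha = 1, K = NULL) {
  if (!is.numeric(rh) || length(rh) != 1L || !is.finite(rh) || rh <= 0) {
    stop("`rh` must be a single positive number (meters)", call. = FALSE)
  }
  .check_population_common(number_density, alpha, K)
  structure(
    list(shape = "sphere", rh = rh, number_density = number_density,
         alpha = alpha, K = K),
    class = "scp_population"
  )
}

#' Rod-shaped particle population
#'
#' Describes a rigid-rod population by length and diameter. Rods diffuse
#' with the orientation-averaged coefficient of
#' [diffusion_coefficient_rod()]; they violate the spherical assumption
#' underlying Stokes-Einstein sizing, so downstream "hydrodynamic radius"
#' estimates for them are equivalent-sphere summaries.
#'
#' @param length,diameter Rod dimensions in meters, `length > diameter`.
#' @param number_density Stock number density in particles per mL.
#' @param alpha,K As in [sphere_population()].
#'
#' @return An object of class `scp_population`.
#' @examples
#' rod_population(400e-9, 20e-9, 1e9)
#' @export
rod_population <- function(length, diameter, number_density,
                           alpha = 1, K = NULL) {
  if (!is.numeric(length) || !is.numeric(diameter) ||
      length(length) != 1L || length(diameter) != 1L ||
      !is.finite(length) || !is.finite(diameter) || diameter <= 0) {
    stop("rod dimensions must be single finite positive numbers",
         call. = FALSE)
  }
  if (length <= diameter) {
    stop("rod aspect ratio must exceed 1 (length > diameter)", call. = FALSE)
  }
  .check_population_common(number_density, alpha, K)
  structure(
    list(shape = "rod", rod_length = length, rod_diameter = diameter,
         number_density = number_density, alpha = alpha, K = K),
    class = "scp_population"
  )
}

.check_population_common <- function(number_density, alpha, K) {
  if (!is.numeric(number_density) || length(number_density) != 1L ||
      !is.finite(number_density) || number_density < 0) {
    stop("`number_density` must be a single non-negative number (per mL)",
         call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L ||
      !is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(K) && (!is.numeric(K) || length(K) != 1L ||
                      !is.finite(K) || K <= 0)) {
    stop("`K` must be NULL or a single positive number", call. = FALSE)
  }
  invisible(NULL)
}

#' @export
print.scp_population <- function(x, ...) {
  if (x$shape == "sphere") {
    cat(sprintf("<population> sphere Rh = %.1f nm, density = %.3g /mL",
                x$rh * 1e9, x$number_density))
  } else {
    cat(sprintf("<population> rod %.0f x %.0f nm, density = %.3g /mL",
                x$rod_length * 1e9, x$rod_diameter * 1e9, x$number_density))
  }
  if (x$alpha < 1) cat(sprintf(", alpha = %.2f", x$alpha))
  cat("\n")
  invisible(x)
}

#' Video acquisition geometry and sampling for nanotracking
#'
#' Describes how trajectories are observed: frame interval, number of
#' frames, the detection volume within which particles are counted and
#' localized (default 15 pL, as typical for interferometric nanotracking
#' instruments), per-frame detection probability, localization noise, and
#' the dilution applied to the sample before measurement.
#'
#' Instrument-level image formation is not modeled: detection is a
#' Bernoulli event per frame on the true in-volume position, plus Gaussian
#' localization noise on the observed x/y coordinates.
#'
#' @param frame_interval Time between frames, seconds.
#' @param n_frames Number of frames recorded (>= 2).
#' @param detection_volume Detection volume in liters (15e-12 = 15 pL).
#' @param field_extent Optional numeric length-3 vector (x, y, z box edges
#'   in meters) for the detection volume; default is a cube of the stated
#'   volume.
#' @param localization_noise_sd Per-axis Gaussian localization error,
#'   meters.
#' @param detection_probability Probability that an in-volume particle is
#'   localized in a given frame, in `[0, 1]`.
#' @param dilution_factor Dilution applied before measurement (>= 1);
#'   densities reported downstream are corrected back by this factor.
#'
#' @return An object of class `scp_acquisition`.
#' @examples
#' acquisition_spec(frame_interval = 0.01, n_frames = 100)
#' @export
acquisition_spec <- function(frame_interval = 0.01,
                             n_frames = 100L,
                             detection_volume = 15e-12,
                             field_extent = NULL,
                             localization_noise_sd = 0,
                             detection_probability = 1,
                             dilution_factor = 1) {
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("`frame_interval` must be > 0", call. = FALSE)
  }
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2L) stop("`n_frames` must be >= 2",
                                             call. = FALSE)
  if (!is.numeric(detection_volume) || detection_volume <= 0) {
    stop("`detection_volume` must be > 0 (liters)", call. = FALSE)
  }
  vol_m3 <- detection_volume * 1e-3  # liters -> m^3
  if (is.null(field_extent)) {
    field_extent <- rep(vol_m3^(1 / 3), 3L)
  }
  if (length(field_extent) != 3L || any(field_extent <= 0)) {
    stop("`field_extent` must be three positive lengths (meters)",
         call. = FALSE)
  }
  if (vol_m3 > prod(field_extent) * (1 + 1e-9)) {
    stop("`detection_volume` exceeds the field_extent box volume",
         call. = FALSE)
  }
  if (!is.numeric(localization_noise_sd) || localization_noise_sd < 0) {
    stop("`localization_noise_sd` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(detection_probability) || detection_probability < 0 ||
      detection_probability > 1) {
    stop("`detection_probability` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(dilution_factor) || dilution_factor < 1) {
    stop("`dilution_factor` must be >= 1", call. = FALSE)
  }
  structure(
    list(frame_interval = frame_interval,
         n_frames = n_frames,
         detection_volume = detection_volume,
         field_extent = field_extent,
         localization_noise_sd = localization_noise_sd,
         detection_probability = detection_probability,
         dilution_factor = dilution_factor),
    class = "scp_acquisition"
  )
}

#' @export
print.scp_acquisition <- function(x, ...) {
  cat(sprintf(
    "<acquisition> dt = %g s, %d frames, V = %.3g pL, p_det = %g, dilution = %gx\n",
    x$frame_interval, x$n_frames, x$detection_volume * 1e12,
    x$detection_probability, x$dilution_factor))
  invisible(x)
}

#' Dynamic light scattering acquisition settings
#'
#' Optical geometry (wavelength, scattering angle), Siegert coherence
#' factor beta, the lag-time grid on which the intensity autocorrelation
#' g2(t) is sampled, and a relative noise level for synthetic correlograms.
#'
#' @param wavelength Laser wavelength in vacuum, meters (default 660 nm).
#' @param angle Scattering angle in degrees, in (0, 180) (default 90).
#' @param beta Coherence (intercept) factor of the Siegert relation, in
#'   (0, 1].
#' @param lag_grid Strictly increasing positive lag times, seconds.
#' @param noise_sd Relative noise level of synthetic g2 curves; realized as
#'   additive zero-mean Gaussian noise with standard deviation
#'   `noise_sd * beta` per lag.
#'
#' @return An object of class `scp_dls_acquisition`.
#' @examples
#' dls_acquisition_spec()
#' @export
dls_acquisition_spec <- function(wavelength = 660e-9,
                                 angle = 90,
                                 beta = 1,
                                 lag_grid = 10^seq(-6, 0, length.out = 200),
                                 noise_sd = 0) {
  if (!is.numeric(wavelength) || wavelength <= 0) {
    stop("`wavelength` must be > 0", call. = FALSE)
  }
  if (!is.numeric(angle) || angle <= 0 || angle >= 180) {
    stop("`angle` must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  }
  if (!is.numeric(beta) || beta <= 0 || beta > 1) {
    stop("`beta` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(lag_grid) || length(lag_grid) < 2L ||
      any(lag_grid <= 0) || any(diff(lag_grid) <= 0)) {
    stop("`lag_grid` must be strictly increasing and positive",
         call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  structure(
    list(wavelength = wavelength, angle = angle, beta = beta,
         lag_grid = lag_grid, noise_sd = noise_sd),
    class = "scp_dls_acquisition"
  )
}

#' @export
print.scp_dls_acquisition <- function(x, ...) {
  cat(sprintf(
    "<DLS acquisition> lambda0 = %.0f nm, theta = %g deg, beta = %g, %d lags in [%.2g, %.2g] s\n",
    x$wavelength * 1e9, x$angle, x$beta, length(x$lag_grid),
    min(x$lag_grid), max(x$lag_grid)))
  invisible(x)
}
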