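# YAML run configuration: one file holds the medium, acquisition, DLS
# settings, population list and seed. Units in config files are the
# human-friendly ones (nm, pL, per-mL); conversion to SI happens here.

#' Read a simulation/analysis configuration from YAML
#'
#' Expected layout (all sections optional; defaults fill gaps):
#' ```yaml
#' seed: 1
#' medium: {temperature: 298.15, viscosity: 8.9e-4, refractive_index: 1.33}
#' acquisition:
#'   frame_interval: 0.01      # s
#'   n_frames: 100
#'   detection_volume_pl: 15
#'   localization_noise_sd_nm: 0
#'   detection_probability: 1
#'   dilution_factor: 1
#' dls:
#'   wavelength_nm: 660
#'   angle_deg: 90
#'   beta: 1
#'   noise_sd: 0
#'   lag_min_s: 1.0e-6
#'   lag_max_s: 1.0
#'   n_lags: 200
#' populations:
#'   - {shape: sphere, rh_nm: 100, number_density_per_ml: 2.0e10, alpha: 1}
#'   - {shape: rod, length_nm: 400, diameter_nm: 20,
#'      number_density_per_ml: 1.0e9}
#' ```
#'
#' @param path Path to the YAML file.
#' @return List with elements `seed`, `medium` ([medium_conditions()]),
#'   `acquisition` ([acquisition_spec()]), `dls`
#'   ([dls_acquisition_spec()]), `populations` (list of population
#'   objects).
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # numbers like 1.0e10 (no exponent sign) arrive as strings from YAML 1.1
  # parsers; coerce every scalar we consume
  g <- function(lst, key, default) {
    v <- if (!is.null(lst[[key]])) lst[[key]] else default
    if (is.character(v) && length(v) == 1L && !is.na(suppressWarnings(
      as.numeric(v)))) v <- as.numeric(v)
    v
  }

  med <- cfg$medium
  medium <- medium_conditions(
    temperature = g(med, "temperature", 298.15),
    viscosity = g(med, "viscosity", 8.9e-4),
    refractive_index = g(med, "refractive_index", 1.33))

  ac <- cfg$acquisition
  acquisition <- acquisition_spec(
    frame_interval = g(ac, "frame_interval", 0.01),
    n_frames = g(ac, "n_frames", 100L),
    detection_volume = g(ac, "detection_volume_pl", 15) * 1e-12,
    localization_noise_sd = g(ac, "localization_noise_sd_nm", 0) * 1e-9,
    detection_probability = g(ac, "detection_probability", 1),
    dilution_factor = g(ac, "dilution_factor", 1))

  dl <- cfg$dls
  dls <- dls_acquisition_spec(
    wavelength = g(dl, "wavelength_nm", 660) * 1e-9,
    angle = g(dl, "angle_deg", 90),
    beta = g(dl, "beta", 1),
    lag_grid = 10^seq(log10(g(dl, "lag_min_s", 1e-6)),
                      log10(g(dl, "lag_max_s", 1)),
                      length.out = g(dl, "n_lags", 200L)),
    noise_sd = g(dl, "noise_sd", 0))

  populations <- lapply(cfg$populations, function(p) {
    shape <- g(p, "shape", "sphere")
    if (shape == "rod") {
      rod_population(g(p, "length_nm", NA) * 1e-9,
                     g(p, "diameter_nm", NA) * 1e-9,
                     g(p, "number_density_per_ml", 0),
                     alpha = g(p, "alpha", 1), K = g(p, "K", NULL))
    } else {
      sphere_population(g(p, "rh_nm", NA) * 1e-9,
                        g(p, "number_density_per_ml", 0),
                        alpha = g(p, "alpha", 1), K = g(p, "K", NULL))
    }
  })

  list(seed = g(cfg, "seed", NULL), medium = medium,
       acquisition = acquisition, dls = dls, populations = populations)
}

#' Path to a bundled study-style summary table
#'
#' The package ships a small example dataset: per-sample multi-method
#' measurements (particle counts by flow cytometry and nanotracking,
#' DLS peak intensity fractions and radii, UV absorbances, replicate
#' errors) for samples derived from blood, spruce-needle homogenate,
#' microalgal flagella suspensions and conditioned media, and liposome
#' preparations at two dilutions. These drive the comparison-stage
#' examples and worked analyses.
#'
#' @param name One of `"particle_counts"`, `"hydrodynamic_radii"`,
#'   `"replicate_errors"`.
#' @return Path to the installed TSV.
#' @examples
#' head(read.delim(study_summary_path("particle_counts")))
#' @export
study_summary_path <- function(name = c("particle_counts",
                                        "hydrodynamic_radii",
                                        "replicate_errors")) {
  name <- match.arg(name)
  system.file("extdata", "study_summary", paste0(name, ".tsv"),
              package = "scpsize", mustWork = TRUE)
}
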