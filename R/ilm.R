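# Per-sample nanotracking summaries: the per-track chain
# MSD -> D -> Rh, averaged across tracks, plus number density from counts
# in the detection volume, with the reporting conventions used in
# multi-method particle characterization tables (SD only when at least 40
# tracks; UDL / LP / BA quality flags).

#' Number density from a particle count in a detection volume
#'
#' Density = count / volume, corrected back to the undiluted stock by the
#' dilution factor.
#'
#' @param n_particles Number of detected particles (may be a fractional
#'   time-average of per-frame counts).
#' @param detection_volume Detection volume in liters.
#' @param dilution_factor Dilution applied before measurement (>= 1).
#'
#' @return Number density in particles per mL.
#' @examples
#' number_density(300, 15e-12, 10)  # 2e11 /mL
#' @export
number_density <- function(n_particles, detection_volume,
                           dilution_factor = 1) {
  if (!is.numeric(n_particles) || any(n_particles < 0)) {
    stop("`n_particles` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(detection_volume) || detection_volume <= 0) {
    stop("`detection_volume` must be > 0 (liters)", call. = FALSE)
  }
  if (!is.numeric(dilution_factor) || dilution_factor < 1) {
    stop("`dilution_factor` must be >= 1", call. = FALSE)
  }
  n_particles / (detection_volume * 1e3) * dilution_factor  # L -> mL
}

#' Per-sample nanotracking summary
#'
#' Runs the sizing chain on every sufficiently long track (MSD, diffusion
#' coefficient, Stokes-Einstein radius), then reports the unweighted mean
#' and -- for at least 40 contributing tracks -- standard deviation of the
#' per-track radii, the stock number density (time-averaged per-frame
#' detected count over the detection volume, dilution-corrected), and
#' quality flags: `UDL` when fewer than `udl_min_tracks` tracks could be
#' sized (mean withheld), `LP` when any track's radius exceeds
#' `lp_rh_threshold`, `BA` as a pass-through annotation.
#'
#' Tracks yielding non-positive diffusion estimates are excluded from the
#' radius statistics and counted in `n_excluded`.
#'
#' @param ts An `scp_trackset`.
#' @param medium A [medium_conditions()] object.
#' @param mode,fit_lags Estimator settings passed to
#'   [diffusion_from_msd()].
#' @param udl_min_tracks Minimum sized-track count below which the sample
#'   is flagged under the detection limit (default 5).
#' @param lp_rh_threshold Radius (meters) above which the large-particle
#'   flag is raised (default 1 micrometer).
#' @param sample Sample label carried into reports.
#' @param ba Pass-through bacteria annotation.
#'
#' @return An object of class `scp_ilm_result`: list with `sample`,
#'   `n_tracked`, `mean_rh`, `sd_rh` (NA unless `n_tracked >= 40`),
#'   `number_density`, `flags`, `n_excluded`, `dilution_factor`, and the
#'   per-track radii `rh` (meters).
#' @examples
#' ts <- simulate_tracks(sphere_population(100e-9, 2.5e10),
#'                       acquisition_spec(n_frames = 60), seed = 1)
#' ilm_summary(ts)
#' @export
ilm_summary <- function(ts, medium = medium_conditions(),
                        mode = c("linear_fit", "lag1"), fit_lags = 4L,
                        udl_min_tracks = 5L, lp_rh_threshold = 1e-6,
                        sample = "", ba = FALSE) {
  stopifnot(inherits(ts, "scp_trackset"))
  .check_medium(medium)
  mode <- match.arg(mode)
  fit_lags <- as.integer(fit_lags)
  need_len <- if (mode == "lag1") 2L else fit_lags + 1L
  dt <- ts$acquisition$frame_interval

  rh <- numeric(0)
  n_excluded <- 0L
  for (tr in ts$tracks) {
    if (length(tr$frames) < need_len) next
    curve <- msd_curve(tr, if (mode == "lag1") 1L else fit_lags, dt)
    if (length(curve$lags) < (if (mode == "lag1") 1L else fit_lags)) next
    est <- diffusion_from_msd(curve, mode, fit_lags)
    if (!is.finite(est$D) || est$D <= 0) {
      n_excluded <- n_excluded + 1L
      next
    }
    rh <- c(rh, rh_from_diffusion(est$D, medium))
  }

  n_tracked <- length(rh)
  flags <- character(0)
  if (n_tracked < udl_min_tracks) flags <- c(flags, "UDL")
  if (n_tracked && any(rh > lp_rh_threshold)) flags <- c(flags, "LP")
  if (isTRUE(ba)) flags <- c(flags, "BA")

  mean_rh <- if (n_tracked && !("UDL" %in% flags)) mean(rh) else NA_real_
  sd_rh <- if (n_tracked >= 40L) stats::sd(rh) else NA_real_

  dens <- number_density(mean(ts$frame_counts),
                         ts$acquisition$detection_volume,
                         ts$acquisition$dilution_factor)

  structure(
    list(sample = sample, n_tracked = n_tracked, mean_rh = mean_rh,
         sd_rh = sd_rh, number_density = dens, flags = flags,
         n_excluded = n_excluded,
         dilution_factor = ts$acquisition$dilution_factor, rh = rh),
    class = "scp_ilm_result"
  )
}

#' @export
print.scp_ilm_result <- function(x, ...) {
  cat("<ILM summary>", format(x), "\n")
  invisible(x)
}

#' @export
format.scp_ilm_result <- function(x, ...) {
  rh_txt <- if ("UDL" %in% x$flags) {
    "UDL"
  } else if (is.na(x$sd_rh)) {
    sprintf("%d  %.0f nm", x$n_tracked, x$mean_rh * 1e9)
  } else {
    sprintf("%d  %.0f ± %.0f nm", x$n_tracked, x$mean_rh * 1e9,
            x$sd_rh * 1e9)
  }
  flag_txt <- if (length(x$flags)) paste0("/", paste(x$flags, collapse = "/"))
    else ""
  sprintf("%s%s  N = %.3g /mL%s",
          if (nzchar(x$sample)) paste0(x$sample, ": ") else "",
          rh_txt, x$number_density, flag_txt)
}

#' Tabulate nanotracking summaries
#'
#' @param results A list of `scp_ilm_result` objects.
#' @return A data.frame with columns `sample`, `dilution`, `n_tracked`,
#'   `mean_rh_nm`, `sd_rh_nm`, `density_per_ml`, `flags` mirroring the
#'   layout of per-sample summary tables.
#' @export
ilm_result_table <- function(results) {
  if (inherits(results, "scp_ilm_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(sample = r$sample, dilution = r$dilution_factor,
               n_tracked = r$n_tracked,
               mean_rh_nm = r$mean_rh * 1e9, sd_rh_nm = r$sd_rh * 1e9,
               density_per_ml = r$number_density,
               flags = paste(r$flags, collapse = "/"))
  }))
}
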