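# Synthetic trajectory generator: Brownian and fractional-Brownian motion
# of spheres and rods inside a finite detection volume, with per-frame
# Bernoulli detection and Gaussian localization noise. This provides
# ground-truthed input for the linking and sizing stages.

# triangle-wave fold into [-h, h]: reflecting walls for the outer
# simulation box, conserving the particle reservoir
.reflect_fold <- function(x, h) {
  z <- (x + h) %% (4 * h)
  ifelse(z < 2 * h, z - h, 3 * h - z)
}

# Effective in-suspension diffusion/transport parameters for one
# population mode. Returns list(alpha, D or K) in SI units.
.mode_motion <- function(mode, acq, medium) {
  D <- if (mode$shape == "sphere") {
    diffusion_coefficient_sphere(mode$rh, medium)
  } else {
    diffusion_coefficient_rod(mode$rod_length, mode$rod_diameter, medium)
  }
  if (mode$alpha >= 1) {
    list(alpha = 1, D = D)
  } else {
    K <- mode$K
    if (is.null(K)) {
      # match the lag-1 MSD of free diffusion: 4 K dt^alpha = 4 D dt
      K <- D * acq$frame_interval^(1 - mode$alpha)
    }
    list(alpha = mode$alpha, K = K)
  }
}

# Lower-triangular factor of the unit-scale fBm position covariance
# C0[i,j] = t_i^a + t_j^a - |t_i - t_j|^a at times t = (1..n)*dt.
# Positions sampled as sqrt(K) * M %*% z give Var[x(t)] = 2 K t^a per axis,
# i.e. a 2-D MSD of 4 K t^a.
.fbm_factor <- function(n, dt, alpha) {
  t <- (1:n) * dt
  C0 <- outer(t, t, function(a, b) a^alpha + b^alpha - abs(a - b)^alpha)
  # tiny jitter guards against numerically semi-definite covariances
  t(chol(C0 + diag(1e-12 * max(C0), n)))
}

#' Simulate nanotracking trajectories in a finite detection volume
#'
#' Particles of each population mode are placed uniformly (Poisson number)
#' in a simulation box of twice the detection volume, diffuse freely in 3-D
#' (ordinary Brownian steps of per-axis variance 2 D dt, or fractional
#' Brownian motion with 2-D MSD exactly 4 K dt^alpha when `alpha < 1`),
#' and are localized in 2-D projection -- only while inside the centered
#' detection box, with probability `detection_probability` per frame, and
#' with additive Gaussian localization noise. Tracks fragment naturally as
#' particles leave and re-enter the detection volume. The outer simulation
#' box has reflecting walls so the particle reservoir stays stationary over
#' arbitrarily long acquisitions; the walls sit well away from the
#' detection volume, so displacement statistics of detected particles are
#' unaffected on the lag scales used for sizing.
#'
#' The number of particles per mode is Poisson with mean
#' `number_density / dilution_factor x simulation volume`, i.e. densities
#' refer to the undiluted stock and the instrument sees the diluted
#' suspension.
#'
#' @param modes A single population or list of populations from
#'   [sphere_population()] / [rod_population()].
#' @param acq An [acquisition_spec()].
#' @param medium A [medium_conditions()] object.
#' @param seed Optional integer seed; identical seeds reproduce identical
#'   track sets bit for bit.
#'
#' @return An `scp_trackset` whose tracks carry the generator's particle
#'   identities as track ids. A `truth` attribute (data.frame with
#'   `track_id`, `mode`, `D` or `K`, `alpha`) records per-track ground
#'   truth for recovery tests.
#' @examples
#' ts <- simulate_tracks(sphere_population(100e-9, 2e10),
#'                       acquisition_spec(n_frames = 20), seed = 1)
#' ts
#' @export
simulate_tracks <- function(modes, acq, medium = medium_conditions(),
                            seed = NULL) {
  if (inherits(modes, "scp_population")) modes <- list(modes)
  if (!length(modes) || !all(vapply(modes, inherits, TRUE, "scp_population"))) {
    stop("`modes` must be one or more population objects", call. = FALSE)
  }
  if (!any(vapply(modes, `[[`, 0, "number_density") > 0)) {
    stop("at least one mode must have positive number_density",
         call. = FALSE)
  }
  stopifnot(inherits(acq, "scp_acquisition"))
  .check_medium(medium)
  if (!is.null(seed)) set.seed(seed)

  n_frames <- acq$n_frames
  dt <- acq$frame_interval
  det_half <- acq$field_extent / 2
  sim_half <- det_half * 2^(1 / 3)  # simulation box: 2x detection volume
  v_sim_m3 <- prod(2 * sim_half)

  tracks <- list()
  truth <- list()
  frame_counts <- integer(n_frames)
  next_id <- 0L

  for (im in seq_along(modes)) {
    mode <- modes[[im]]
    if (mode$number_density <= 0) next
    dens_m3 <- mode$number_density * 1e6 / acq$dilution_factor
    n_part <- stats::rpois(1L, dens_m3 * v_sim_m3)
    if (n_part == 0L) next
    mot <- .mode_motion(mode, acq, medium)
    fbm_M <- if (mot$alpha < 1) .fbm_factor(n_frames - 1L, dt, mot$alpha)

    # start positions uniform in the simulation box, per axis
    pos <- array(NA_real_, dim = c(n_frames, n_part, 3L))
    for (ax in 1:3) {
      start <- stats::runif(n_part, -sim_half[ax], sim_half[ax])
      if (mot$alpha == 1) {
        inc <- matrix(stats::rnorm((n_frames - 1L) * n_part,
                                   sd = sqrt(2 * mot$D * dt)),
                      n_frames - 1L, n_part)
        offs <- apply(inc, 2L, cumsum)
        if (n_frames == 2L) offs <- matrix(offs, 1L, n_part)
      } else {
        z <- matrix(stats::rnorm((n_frames - 1L) * n_part),
                    n_frames - 1L, n_part)
        offs <- sqrt(mot$K) * (fbm_M %*% z)
      }
      pos[, , ax] <- .reflect_fold(rbind(start, sweep(offs, 2L, start, `+`)),
                                   sim_half[ax])
    }

    inside <- abs(pos[, , 1]) <= det_half[1] &
      abs(pos[, , 2]) <= det_half[2] &
      abs(pos[, , 3]) <= det_half[3]
    detected <- inside &
      (matrix(stats::runif(n_frames * n_part), n_frames, n_part) <
         acq$detection_probability)

    frame_counts <- frame_counts + rowSums(detected)

    if (acq$localization_noise_sd > 0) {
      obs_x <- pos[, , 1] + stats::rnorm(n_frames * n_part,
                                         sd = acq$localization_noise_sd)
      obs_y <- pos[, , 2] + stats::rnorm(n_frames * n_part,
                                         sd = acq$localization_noise_sd)
    } else {
      obs_x <- pos[, , 1]
      obs_y <- pos[, , 2]
    }
    obs_x <- matrix(obs_x, n_frames, n_part)
    obs_y <- matrix(obs_y, n_frames, n_part)

    for (j in seq_len(n_part)) {
      f <- which(detected[, j])
      if (length(f) < 2L) next
      next_id <- next_id + 1L
      id <- as.character(next_id)
      tracks[[length(tracks) + 1L]] <-
        new_track(id, f - 1L, obs_x[f, j], obs_y[f, j])
      truth[[length(truth) + 1L]] <- data.frame(
        track_id = id, mode = im,
        D = if (mot$alpha == 1) mot$D else NA_real_,
        K = if (mot$alpha < 1) mot$K else NA_real_,
        alpha = mot$alpha)
    }
  }

  ts <- track_set(tracks, acq,
                  provenance = sprintf("simulate_tracks(seed=%s)",
                                       if (is.null(seed)) "NULL" else seed),
                  frame_counts = frame_counts)
  attr(ts, "truth") <- if (length(truth)) do.call(rbind, truth) else
    data.frame(track_id = character(), mode = integer(), D = numeric(),
               K = numeric(), alpha = numeric())
  ts
}
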