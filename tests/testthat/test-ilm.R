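test_that("MSD of degenerate tracks has the closed forms", {
  dt <- 0.01
  still <- new_track(1, 0:9, rep(1e-6, 10), rep(2e-6, 10))
  expect_true(all(msd_curve(still, 3, dt)$msd == 0))
  # ballistic drift at 100 nm / frame: msd(m) = (100 m nm)^2
  v <- 100e-9
  ball <- msd_curve(new_track(1, 0:20, (0:20) * v, numeric(21)), 4, dt)
  expect_equal(ball$msd, (v * (1:4))^2, tolerance = 1e-12)
  expect_equal(ball$msd[2] / ball$msd[1], 4, tolerance = 1e-12)
})

test_that("gap-bridged frames contribute no displacement pairs", {
  dt <- 0.01
  tr <- new_track(1, c(0, 1, 3, 4), c(0, 1, 3, 4) * 1e-7, numeric(4))
  curve <- msd_curve(tr, 2, dt)
  expect_equal(curve$n_pairs, c(2L, 1L))  # lag1: (0,1),(3,4); lag2: (1,3)
  expect_error(msd_curve(tr, 4, dt), "track length")
})

test_that("MSD of a long Brownian track matches 4 D dt", {
  dt <- 0.01
  set.seed(17)
  n <- 1e4
  sd_step <- sqrt(2 * D_100NM * dt)
  tr <- new_track(1, 0:n, cumsum(c(0, rnorm(n, sd = sd_step))),
                  cumsum(c(0, rnorm(n, sd = sd_step))))
  curve <- msd_curve(tr, 1, dt)
  se <- sqrt(8) * D_100NM * dt * 2 / sqrt(n)  # sd(d^2)/sqrt(n), d^2 ~ 2D chi
  expect_lt(abs(curve$msd[1] - 4 * D_100NM * dt), 3 * se)
})

test_that("diffusion estimators have the documented closed-form behavior", {
  dt <- 0.01
  lin <- structure(list(lags = (1:6) * dt, msd = 4 * 3e-12 * (1:6) * dt,
                        n_pairs = rep(50L, 6)), class = "scp_msd")
  for (fl in c(2, 4, 6)) {
    expect_equal(diffusion_from_msd(lin, "linear_fit", fl)$D, 3e-12,
                 tolerance = 1e-9)
  }
  expect_equal(diffusion_from_msd(lin, "lag1")$D, 3e-12, tolerance = 1e-12)
  # constant curve: noise-only plateau
  const <- structure(list(lags = (1:4) * dt, msd = rep(2e-14, 4),
                          n_pairs = rep(50L, 4)), class = "scp_msd")
  fit <- diffusion_from_msd(const, "linear_fit", 4)
  expect_equal(fit$D, 0, tolerance = 1e-20)
  expect_equal(fit$flag, "nonphysical")
  expect_equal(diffusion_from_msd(const, "lag1")$D, 2e-14 / (4 * dt),
               tolerance = 1e-12)
  # decreasing curve yields a negative, flagged estimate
  dec <- structure(list(lags = (1:4) * dt, msd = rev((1:4)) * 1e-14,
                        n_pairs = rep(50L, 4)), class = "scp_msd")
  expect_lt(diffusion_from_msd(dec, "linear_fit", 4)$D, 0)
  expect_equal(diffusion_from_msd(dec, "linear_fit", 4)$flag, "nonphysical")
})

test_that("lag-1 worked value inverts to 100 nm", {
  # msd(dt) = 9.815e-14 m^2 at dt = 0.01 s -> D -> Rh = 100 nm
  curve <- structure(list(lags = 0.01, msd = 4 * D_100NM * 0.01,
                          n_pairs = 100L), class = "scp_msd")
  D <- diffusion_from_msd(curve, "lag1")$D
  expect_equal(D, D_100NM, tolerance = 1e-12)
  expect_equal(rh_from_diffusion(D), 100e-9, tolerance = 1e-9)
  # at fixed D, Rh = kT/(6 pi eta D) is inversely proportional to viscosity
  expect_equal(rh_from_diffusion(D, medium_conditions(viscosity = 2 * 8.9e-4)),
               50e-9, tolerance = 1e-9)
})

test_that("number density arithmetic and guards", {
  expect_equal(number_density(300, 15e-12, 10), 2e11, tolerance = 1e-12)
  expect_equal(number_density(300, 15e-12, 1),
               number_density(300, 15e-12), tolerance = 1e-15)
  expect_equal(number_density(0, 15e-12), 0)
  expect_error(number_density(-1, 15e-12), ">= 0")
  expect_error(number_density(10, 0), "> 0")
  expect_error(number_density(10, 15e-12, 0.5), ">= 1")
})

test_that("summary reporting rules: SD threshold, UDL, LP, exclusions", {
  dt <- 0.01
  acq <- acquisition_spec(frame_interval = dt, n_frames = 60)
  mk_brownian <- function(id, D, n = 59) {
    s <- sqrt(2 * D * dt)
    new_track(id, 0:n, cumsum(c(0, rnorm(n, sd = s))),
              cumsum(c(0, rnorm(n, sd = s))))
  }
  set.seed(23)
  tracks39 <- lapply(1:39, mk_brownian, D = D_100NM)
  res39 <- ilm_summary(track_set(tracks39, acq))
  expect_equal(res39$n_tracked, 39L)
  expect_true(is.na(res39$sd_rh))
  res40 <- ilm_summary(track_set(lapply(1:40, mk_brownian, D = D_100NM),
                                 acq))
  expect_false(is.na(res40$sd_rh))
  # mean/SD equal direct recomputation from the per-track radii
  expect_equal(res40$mean_rh, mean(res40$rh), tolerance = 1e-12)
  expect_equal(res40$sd_rh, sd(res40$rh), tolerance = 1e-12)

  # a giant slow particle raises the LP flag
  slow <- mk_brownian("big", diffusion_coefficient_sphere(2e-6))
  res_lp <- ilm_summary(track_set(c(tracks39, list(slow)), acq))
  expect_true("LP" %in% res_lp$flags)

  # too few tracks: UDL, mean withheld
  res_udl <- ilm_summary(track_set(tracks39[1:3], acq))
  expect_true("UDL" %in% res_udl$flags)
  expect_true(is.na(res_udl$mean_rh))
  # empty set is legal
  expect_true("UDL" %in% ilm_summary(track_set(list(), acq))$flags)

  # a stationary track gives D = 0 under linear_fit: excluded and tallied
  still <- new_track("still", 0:59, rep(0, 60), rep(0, 60))
  res_ex <- ilm_summary(track_set(c(tracks39, list(still)), acq))
  expect_equal(res_ex$n_excluded, 1L)
  expect_equal(res_ex$n_tracked, 39L)

  # BA is pass-through
  expect_true("BA" %in% ilm_summary(track_set(tracks39, acq), ba = TRUE)$flags)
})

test_that("summary formatting follows the N / Rh +/- SD convention", {
  dt <- 0.01
  acq <- acquisition_spec(frame_interval = dt, n_frames = 60)
  set.seed(9)
  mk <- function(id) {
    s <- sqrt(2 * D_100NM * dt)
    new_track(id, 0:59, cumsum(c(0, rnorm(59, sd = s))),
              cumsum(c(0, rnorm(59, sd = s))))
  }
  res <- ilm_summary(track_set(lapply(1:45, mk), acq), sample = "SYN")
  txt <- format(res)
  expect_match(txt, "^SYN: 45  \\d+ ± \\d+ nm")
  tab <- ilm_result_table(res)
  expect_named(tab, c("sample", "dilution", "n_tracked", "mean_rh_nm",
                      "sd_rh_nm", "density_per_ml", "flags"))
})

test_that("localization noise inflates lag-1 D but not the intercept fit", {
  sigma <- 20e-9
  dens <- density_for_count(700)
  acq <- acquisition_spec(frame_interval = 0.01, n_frames = 201,
                          localization_noise_sd = sigma)
  ts <- suppressMessages(filter_tracks(
    simulate_tracks(sphere_population(100e-9, dens), acq, seed = 55), 201))
  expect_gte(length(ts), 300)
  fit <- ilm_summary(ts, mode = "linear_fit", fit_lags = 4)
  lag1 <- ilm_summary(ts, mode = "lag1")
  # the free intercept absorbs the 4 sigma^2 offset
  expect_lt(abs(fit$mean_rh - 100e-9), 10e-9)
  # lag-1 apparent D exceeds the true D (noise adds 4 sigma^2 to MSD) ...
  D_hat <- vapply(ts$tracks, function(tr) {
    diffusion_from_msd(msd_curve(tr, 1, 0.01), "lag1")$D
  }, 0)
  expect_gt(mean(D_hat), diffusion_coefficient_sphere(100e-9))
  # ... so the lag-1 radius is biased low relative to the intercept fit
  expect_lt(lag1$mean_rh, fit$mean_rh)
})
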