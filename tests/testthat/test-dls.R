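test_that("scattering vector matches direct evaluation and scales correctly", {
  q <- scattering_vector(medium_conditions(), 660e-9, 90)
  expect_equal(q, Q_REF, tolerance = 1e-9)
  # sin(theta/2) -> 1 near backscatter
  q_back <- scattering_vector(medium_conditions(), 660e-9, 179.99)
  expect_equal(q_back, 4 * pi * 1.33 / 660e-9, tolerance = 1e-6)
  expect_equal(scattering_vector(medium_conditions(), 330e-9, 90), 2 * q,
               tolerance = 1e-12)
  expect_error(scattering_vector(medium_conditions(), 660e-9, 180), "angle")
  expect_error(scattering_vector(medium_conditions(), 660e-9, 0), "angle")
})

test_that("Siegert reduction and its round trip are exact", {
  cf <- correlation_function(c(1e-4, 1e-2), c(1.5, 1.0), beta = 0.5)
  g1 <- g1_from_g2(cf)
  expect_equal(as.numeric(g1[1]), 1, tolerance = 1e-12)
  expect_equal(as.numeric(g1[2]), 0, tolerance = 1e-12)

  # noiseless generator round trip at 1e-12
  modes <- list(sphere_population(50e-9, 64e9),
                sphere_population(100e-9, 1e9))
  dls <- dls_acquisition_spec(beta = 0.7)
  cf2 <- simulate_dls_g2(modes, dls)
  truth <- attr(cf2, "truth")
  g1_true <- colSums(truth$weight * exp(-outer(truth$gamma, cf2$lags)))
  g1_back <- as.numeric(g1_from_g2(cf2))
  # 1e-12 wherever (g2 - 1) is not lost to double-precision cancellation
  solid <- g1_true > 1e-3
  expect_lt(max(abs(g1_back[solid] - g1_true[solid])), 1e-12)
  expect_lt(max(abs(g1_back - g1_true)), 1e-6)

  # below-baseline noise is clipped and counted
  noisy <- correlation_function(c(1e-4, 1e-2), c(1.2, 0.999), beta = 1)
  g1n <- g1_from_g2(noisy)
  expect_equal(attr(g1n, "n_clipped"), 1L)
  expect_equal(as.numeric(g1n[2]), 0)
})

test_that("beta is recovered from the short-lag intercept", {
  dls <- dls_acquisition_spec(beta = 0.63)
  cf <- simulate_dls_g2(sphere_population(100e-9, 1e10), dls)
  cf$beta <- NULL
  expect_equal(estimate_beta(cf), 0.63, tolerance = 1e-3)
})

test_that("single-exponential inversion localizes the decay rate", {
  t <- 10^seq(-6, 0, length.out = 200)
  sp <- invert_decay_spectrum(exp(-GAMMA_100NM * t), t)
  gbar <- sum(sp$weights * sp$gamma)
  spacing <- sp$gamma[2] / sp$gamma[1]
  expect_lt(abs(log(gbar / GAMMA_100NM)), log(spacing))
  expect_equal(sum(sp$weights), 1, tolerance = 1e-12)
})

test_that("unregularized solution matches the closed-form oracle on-grid", {
  t <- 10^seq(-6, 0, length.out = 200)
  n <- 50
  center <- sqrt(1 / min(t) / max(t))
  gam <- 10^seq(log10(center) - 3, log10(center) + 3, length.out = n)
  k <- which.min(abs(gam - GAMMA_100NM))
  sp <- invert_decay_spectrum(exp(-gam[k] * t), t, n_exponents = n,
                              gamma_span = 6, reg_strength = 0)
  expected <- numeric(n)
  expected[k] <- 1
  expect_lt(max(abs(sp$weights - expected)), 1e-8)
})

test_that("well-separated mixtures are resolved with correct fractions", {
  t <- 10^seq(-6, 0, length.out = 200)
  g1 <- 0.5 * exp(-200 * t) + 0.5 * exp(-3200 * t)  # Gamma ratio 16
  sp <- invert_decay_spectrum(g1, t)
  dist <- size_distribution(sp, Q_REF)
  peaks <- peaks_from_distribution(dist)
  expect_equal(nrow(peaks), 2)
  expect_equal(peaks$fraction, c(0.5, 0.5), tolerance = 0.1)
  rh_expected <- sort(rh_from_gamma(c(200, 3200), Q_REF))
  expect_equal(peaks$rh, rh_expected, tolerance = 0.15)
})

test_that("a non-decaying correlation puts all weight in the slowest bins", {
  t <- 10^seq(-6, 0, length.out = 150)
  sp <- invert_decay_spectrum(rep(1, length(t)), t)
  # weighted-mean decay rate pinned to the slow end of the grid
  expect_lt(sum(sp$weights * sp$gamma), 10 * min(sp$gamma))
  peaks <- peaks_from_distribution(size_distribution(sp, Q_REF))
  expect_true(any(peaks$lp))  # Rh beyond 10 um: very-large-particle flag
})

test_that("inversion is invariant to overall scaling of g1", {
  t <- 10^seq(-6, 0, length.out = 200)
  g1 <- 0.4 * exp(-300 * t) + 0.6 * exp(-5000 * t)
  a <- invert_decay_spectrum(g1, t, reg_strength = 1e-4)
  b <- invert_decay_spectrum(3 * g1, t, reg_strength = 1e-4)
  expect_equal(which.max(a$weights), which.max(b$weights))
  expect_equal(a$weights, b$weights, tolerance = 1e-4)
})

test_that("smoothing monotonically reduces the spectrum's total variation", {
  t <- 10^seq(-6, 0, length.out = 200)
  g1 <- 0.5 * exp(-200 * t) + 0.5 * exp(-3200 * t)
  tv <- vapply(c(0, 1e-4, 1e-2, 1, 100), function(l) {
    w <- invert_decay_spectrum(g1, t, reg_strength = l)$weights
    sum(abs(diff(w)))
  }, 0)
  expect_true(all(diff(tv) <= 1e-9))
})

test_that("invalid inversion inputs are rejected", {
  t <- 10^seq(-5, -1, length.out = 120)
  expect_error(invert_decay_spectrum(numeric(length(t)) , t), "all-zero")
  expect_error(invert_decay_spectrum(exp(-100 * t), t, n_exponents = 1),
               "2, 50")
  expect_error(invert_decay_spectrum(exp(-100 * t), t, n_exponents = 51),
               "2, 50")
  expect_warning(invert_decay_spectrum(exp(-100 * t[1:40]), t[1:40],
                                       n_exponents = 50),
                 "underdetermined")
})

test_that("decay-rate to radius mapping composes with the worked values", {
  expect_equal(rh_from_gamma(GAMMA_100NM, Q_REF), 100e-9, tolerance = 1e-6)
  expect_equal(rh_from_gamma(2 * GAMMA_100NM, Q_REF), 50e-9,
               tolerance = 1e-6)
  expect_error(rh_from_gamma(-1, Q_REF), "> 0")
})

test_that("peak extraction reports fractions in ascending radius order", {
  # hand-built distribution with three separated populations
  rh_grid <- 10^seq(-8, -4.5, length.out = 60)
  w <- numeric(60)
  w[8:10] <- c(0.04, 0.08, 0.04)    # 0.16 small
  w[25:27] <- c(0.15, 0.32, 0.15)   # 0.62 main
  w[45:47] <- c(0.05, 0.12, 0.05)   # 0.22 large
  dist <- structure(list(rh_grid = rh_grid, weights = w,
                         gamma = rev(rh_grid), i_tot = NA_real_),
                    class = "scp_size_distribution")
  peaks <- peaks_from_distribution(dist)
  expect_equal(nrow(peaks), 3)
  expect_true(all(diff(peaks$rh) > 0))
  expect_equal(peaks$fraction, c(0.16, 0.62, 0.22), tolerance = 1e-9)
  expect_lte(sum(peaks$fraction), 1 + 1e-9)
  expect_true(all(peaks$fraction >= 0 & peaks$fraction <= 1))
  # the main (highest-fraction) peak is the middle one by radius
  expect_equal(which.max(peaks$fraction), 2L)

  # single contiguous peak carries all intensity
  w1 <- numeric(60); w1[20:24] <- 0.2
  d1 <- structure(list(rh_grid = rh_grid, weights = w1 / sum(w1),
                       gamma = rev(rh_grid), i_tot = NA_real_),
                  class = "scp_size_distribution")
  p1 <- peaks_from_distribution(d1)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$fraction, 1.0, tolerance = 1e-12)

  # a peak beyond 10 um is flagged
  w2 <- w; w2[58:60] <- 0.3
  d2 <- structure(list(rh_grid = rh_grid, weights = w2 / sum(w2),
                       gamma = rev(rh_grid), i_tot = NA_real_),
                  class = "scp_size_distribution")
  p2 <- peaks_from_distribution(d2)
  expect_lte(nrow(p2), 4)
  expect_true(p2$lp[which.max(p2$rh)])
})

test_that("the full correlogram-to-peaks chain recovers a synthetic mode", {
  cf <- simulate_dls_g2(sphere_population(100e-9, 1e10),
                        dls_acquisition_spec())
  fit <- fit_size_distribution(cf)
  expect_equal(nrow(fit$peaks), 1)
  spacing <- fit$distribution$rh_grid[2] / fit$distribution$rh_grid[1]
  expect_lt(abs(log(fit$peaks$rh / 100e-9)), log(spacing))
})
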