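# DLS inference: Siegert reduction g2 -> g1, regularized non-negative
# inverse-Laplace inversion of g1 onto a log-spaced decay-rate grid
# (CONTIN-style: smoothness-penalized NNLS, at most 50 exponents), mapping
# to an intensity-weighted size distribution, and peak extraction with
# intensity fractions.

#' Scattering vector magnitude
#'
#' q = (4 pi n0 / lambda0) sin(theta / 2).
#'
#' @param medium A [medium_conditions()] object (supplies n0).
#' @param wavelength Vacuum wavelength in meters.
#' @param angle Scattering angle in degrees, strictly between 0 and 180.
#'
#' @return q in 1/meters.
#' @examples
#' scattering_vector(medium_conditions(), 660e-9, 90)  # ~1.79e7 1/m
#' @export
scattering_vector <- function(medium = medium_conditions(),
                              wavelength = 660e-9, angle = 90) {
  .check_medium(medium)
  if (!is.numeric(wavelength) || wavelength <= 0) {
    stop("`wavelength` must be > 0", call. = FALSE)
  }
  if (!is.numeric(angle) || angle <= 0 || angle >= 180) {
    stop("`angle` must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  }
  4 * pi * medium$refractive_index / wavelength * sin(angle * pi / 360)
}

#' Estimate the Siegert coherence factor from short lags
#'
#' Fits log(g2 - 1) linearly in t over the first `n_lags` lags with
#' g2 > 1 and extrapolates to t = 0; the exponentiated intercept is beta.
#' Valid when the shortest lags are well within the initial decay.
#'
#' @param cf An [correlation_function()] object.
#' @param n_lags Number of leading lags used (default 5).
#' @return Estimated beta, capped at 1.
#' @export
estimate_beta <- function(cf, n_lags = 5L) {
  stopifnot(inherits(cf, "scp_correlation"))
  ok <- which(cf$g2 > 1)
  ok <- ok[seq_len(min(n_lags, length(ok)))]
  if (length(ok) < 2L) {
    stop("not enough lags with g2 > 1 to estimate beta", call. = FALSE)
  }
  fit <- stats::lm(log(cf$g2[ok] - 1) ~ cf$lags[ok])
  min(1, exp(unname(stats::coef(fit)[1L])))
}

#' Field correlation from the intensity correlation (Siegert relation)
#'
#' g1(t) = sqrt(max(0, (g2(t) - 1) / beta)). Negative radicands (noise at
#' long lags) are clipped to zero and counted.
#'
#' @param cf An [correlation_function()] object. If its `beta` is `NULL`
#'   it is estimated with [estimate_beta()].
#'
#' @return Numeric vector of g1 values per lag, with attributes
#'   `n_clipped` (number of clipped lags) and `beta` (the value used).
#' @examples
#' cf <- correlation_function(c(1e-4, 1e-3), c(1.5, 1.1), beta = 0.5)
#' g1_from_g2(cf)
#' @export
g1_from_g2 <- function(cf) {
  stopifnot(inherits(cf, "scp_correlation"))
  beta <- cf$beta
  if (is.null(beta)) beta <- estimate_beta(cf)
  if (beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  rad <- (cf$g2 - 1) / beta
  n_clipped <- sum(rad < 0)
  g1 <- sqrt(pmax(0, rad))
  attr(g1, "n_clipped") <- n_clipped
  attr(g1, "beta") <- beta
  g1
}

# second-difference (curvature) operator, (n-2) x n
.second_diff <- function(n) {
  if (n < 3L) return(matrix(0, 0L, n))
  L <- matrix(0, n - 2L, n)
  for (i in seq_len(n - 2L)) L[i, i:(i + 2L)] <- c(1, -2, 1)
  L
}

# smoothness-penalized NNLS: min ||A w - g1||^2 + lambda ||L w||^2, w >= 0
.solve_penalized_nnls <- function(A, g1, L, lambda) {
  if (lambda > 0 && nrow(L)) {
    Aa <- rbind(A, sqrt(lambda) * L)
    ba <- c(g1, numeric(nrow(L)))
  } else {
    Aa <- A
    ba <- g1
  }
  sol <- pracma::lsqnonneg(Aa, ba)
  if (any(!is.finite(sol$x))) {
    stop("non-negative least squares failed to converge; ",
         "residual = ", format(sol$resnorm), call. = FALSE)
  }
  sol$x
}

#' Regularized inverse-Laplace decay spectrum
#'
#' Recovers a non-negative weight spectrum w over a log-spaced grid of
#' decay rates Gamma from the field correlation: minimizes
#' \eqn{\|A w - g_1\|^2 + \lambda \|L w\|^2} subject to \eqn{w \ge 0},
#' where \eqn{A_{jk} = \exp(-\Gamma_k t_j)} and L is a second-difference
#' smoothness operator -- the standard constrained-regularization
#' formulation of CONTIN-style correlogram analysis. Weights are
#' normalized to sum 1.
#'
#' The regularization strength may be fixed, or `"auto"`: the solver
#' scans a logarithmic lambda grid and keeps the largest lambda whose fit
#' residual stays within 20 percent of the best achievable residual -- a
#' discrepancy-style rule that applies the most smoothing consistent with
#' the data. (On a non-negativity-constrained problem with an off-grid
#' decay rate the classical L-curve has no usable corner: the residual
#' floor is set by grid mismatch, not noise.)
#'
#' @param g1 Field correlation values (e.g. from [g1_from_g2()]).
#' @param lags Lag times in seconds, same length as `g1`.
#' @param n_exponents Number of grid points, between 2 and 50.
#' @param gamma_span Width of the Gamma grid in decades (default 6),
#'   centered on the geometric mean of the reciprocal lag range.
#' @param reg_strength Non-negative penalty weight, or `"auto"`.
#'
#' @return An object of class `scp_decay_spectrum`: list with `gamma`
#'   (1/s, increasing), `weights` (sum 1), `reg_strength` (value used),
#'   `residual` (fit residual norm).
#' @examples
#' t <- 10^seq(-5, -1, length.out = 100)
#' sp <- invert_decay_spectrum(exp(-800 * t), t, reg_strength = 0)
#' sp$gamma[which.max(sp$weights)]
#' @export
invert_decay_spectrum <- function(g1, lags, n_exponents = 50L,
                                  gamma_span = 6, reg_strength = "auto") {
  g1 <- as.numeric(g1)
  if (length(g1) != length(lags)) {
    stop("`g1` and `lags` must have equal length", call. = FALSE)
  }
  if (all(g1 == 0)) stop("all-zero g1: no decay to invert", call. = FALSE)
  n_exponents <- as.integer(n_exponents)
  if (n_exponents < 2L || n_exponents > 50L) {
    stop("`n_exponents` must lie in [2, 50]", call. = FALSE)
  }
  if (length(lags) < 2L * n_exponents) {
    warning("fewer than 2 lag points per exponent; ",
            "the inversion may be underdetermined")
  }
  center <- sqrt(1 / min(lags) * 1 / max(lags))
  gamma <- 10^seq(log10(center) - gamma_span / 2,
                  log10(center) + gamma_span / 2,
                  length.out = n_exponents)
  A <- exp(-outer(lags, gamma))
  L <- .second_diff(n_exponents)

  if (identical(reg_strength, "auto")) {
    lambdas <- 10^seq(-6, 2, length.out = 17)
    rho <- numeric(length(lambdas))
    ws <- vector("list", length(lambdas))
    for (i in seq_along(lambdas)) {
      w <- .solve_penalized_nnls(A, g1, L, lambdas[i])
      ws[[i]] <- w
      rho[i] <- sqrt(sum((A %*% w - g1)^2))
    }
    # most smoothing consistent with the fit: largest lambda within 20%
    # of the best achievable residual
    pick <- max(which(rho <= 1.2 * min(rho)))
    w <- ws[[pick]]
    lambda_used <- lambdas[pick]
    residual <- rho[pick]
  } else {
    if (!is.numeric(reg_strength) || reg_strength < 0) {
      stop("`reg_strength` must be >= 0 or \"auto\"", call. = FALSE)
    }
    w <- .solve_penalized_nnls(A, g1, L, reg_strength)
    lambda_used <- reg_strength
    residual <- sqrt(sum((A %*% w - g1)^2))
  }
  s <- sum(w)
  if (s <= 0) stop("inversion returned an empty distribution",
                   call. = FALSE)
  structure(
    list(gamma = gamma, weights = w / s, reg_strength = lambda_used,
         residual = residual),
    class = "scp_decay_spectrum"
  )
}

#' @export
print.scp_decay_spectrum <- function(x, ...) {
  cat(sprintf(
    "<decay spectrum> %d rates in [%.3g, %.3g] 1/s, lambda = %.3g, mode at %.4g 1/s\n",
    length(x$gamma), min(x$gamma), max(x$gamma), x$reg_strength,
    x$gamma[which.max(x$weights)]))
  invisible(x)
}

#' Hydrodynamic radius from a decay rate
#'
#' A diffusing sphere's field correlation decays at Gamma = q^2 D, so
#' D = Gamma / q^2 and Rh = kT / (6 pi eta D).
#'
#' @param gamma Decay rate(s) in 1/s.
#' @param q Scattering vector in 1/m (see [scattering_vector()]).
#' @param medium A [medium_conditions()] object.
#'
#' @return Hydrodynamic radius in meters.
#' @examples
#' q <- scattering_vector()
#' rh_from_gamma(786.74, q)  # ~1e-7 m
#' @export
rh_from_gamma <- function(gamma, q, medium = medium_conditions()) {
  if (!is.numeric(gamma) || any(gamma <= 0)) {
    stop("`gamma` must be > 0", call. = FALSE)
  }
  if (!is.numeric(q) || q <= 0) stop("`q` must be > 0", call. = FALSE)
  rh_from_diffusion(gamma / q^2, medium)
}

#' Map a decay spectrum to an intensity-weighted size distribution
#'
#' @param spectrum An [invert_decay_spectrum()] result.
#' @param q Scattering vector in 1/m.
#' @param medium A [medium_conditions()] object.
#' @param i_tot Optional pass-through total scattered intensity (units as
#'   measured, e.g. kHz/mW); never computed here.
#'
#' @return An object of class `scp_size_distribution`: list with
#'   `rh_grid` (meters, increasing), `weights` (sum 1), `gamma` (1/s,
#'   aligned with `rh_grid`), `i_tot`.
#' @export
size_distribution <- function(spectrum, q, medium = medium_conditions(),
                              i_tot = NA_real_) {
  stopifnot(inherits(spectrum, "scp_decay_spectrum"))
  rh <- rh_from_gamma(spectrum$gamma, q, medium)
  ord <- order(rh)  # large Gamma = small Rh; flip to ascending radius
  structure(
    list(rh_grid = rh[ord], weights = spectrum$weights[ord],
         gamma = spectrum$gamma[ord], i_tot = i_tot),
    class = "scp_size_distribution"
  )
}

#' @export
print.scp_size_distribution <- function(x, ...) {
  cat(sprintf(
    "<size distribution> %d bins, Rh in [%.3g, %.3g] nm, mode at %.4g nm\n",
    length(x$rh_grid), min(x$rh_grid) * 1e9, max(x$rh_grid) * 1e9,
    x$rh_grid[which.max(x$weights)] * 1e9))
  invisible(x)
}

#' Extract peaks and intensity fractions from a size distribution
#'
#' Contiguous runs of bins with weight at least `floor_frac` of the
#' maximum form peaks; each reports its intensity-weighted mean radius and
#' its intensity fraction (sum of weights). Peaks below `min_fraction`
#' are dropped, at most `max_peaks` (largest fractions) are kept, and
#' peaks are returned in ascending radius. A peak whose mean radius
#' exceeds `lp_threshold` (default 10 micrometers) carries the
#' very-large-particle flag.
#'
#' @param dist An [size_distribution()] object (normalized weights).
#' @param min_fraction Smallest reportable intensity fraction.
#' @param floor_frac Bins below this fraction of the maximum weight count
#'   as empty (separates peaks; default 1e-4).
#' @param max_peaks Maximum number of peaks reported (default 4).
#' @param lp_threshold Radius (meters) above which a peak is flagged.
#'
#' @return A data.frame with columns `rh` (meters), `fraction`, `lp`
#'   (logical), sorted by ascending `rh`.
#' @export
peaks_from_distribution <- function(dist, min_fraction = 0.01,
                                    floor_frac = 1e-4, max_peaks = 4L,
                                    lp_threshold = 10e-6) {
  stopifnot(inherits(dist, "scp_size_distribution"))
  w <- dist$weights
  active <- w >= floor_frac * max(w)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- list()
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    frac <- sum(w[idx])
    if (frac < min_fraction) next
    peaks[[length(peaks) + 1L]] <- data.frame(
      rh = sum(w[idx] * dist$rh_grid[idx]) / frac, fraction = frac)
  }
  if (!length(peaks)) {
    return(data.frame(rh = numeric(), fraction = numeric(),
                      lp = logical()))
  }
  out <- do.call(rbind, peaks)
  out <- out[order(-out$fraction), , drop = FALSE]
  out <- out[seq_len(min(nrow(out), max_peaks)), , drop = FALSE]
  out <- out[order(out$rh), , drop = FALSE]
  out$lp <- out$rh > lp_threshold
  rownames(out) <- NULL
  out
}

#' Full DLS sizing chain: correlogram to peak table
#'
#' Convenience wrapper: Siegert reduction, inverse-Laplace inversion,
#' size mapping and peak extraction in one call.
#'
#' @param cf An [correlation_function()] object.
#' @param medium A [medium_conditions()] object.
#' @param wavelength,angle Optical geometry for the scattering vector.
#' @param n_exponents,gamma_span,reg_strength Passed to
#'   [invert_decay_spectrum()].
#' @param ... Passed to [peaks_from_distribution()].
#'
#' @return List with `distribution` (`scp_size_distribution`), `peaks`
#'   (data.frame), `spectrum` (`scp_decay_spectrum`), `q` and `beta`.
#' @examples
#' cf <- simulate_dls_g2(sphere_population(100e-9, 1e10),
#'                       dls_acquisition_spec())
#' fit <- fit_size_distribution(cf)
#' fit$peaks
#' @export
fit_size_distribution <- function(cf, medium = medium_conditions(),
                                  wavelength = 660e-9, angle = 90,
                                  n_exponents = 50L, gamma_span = 6,
                                  reg_strength = "auto", ...) {
  g1 <- g1_from_g2(cf)
  spectrum <- invert_decay_spectrum(g1, cf$lags, n_exponents, gamma_span,
                                    reg_strength)
  q <- scattering_vector(medium, wavelength, angle)
  dist <- size_distribution(spectrum, q, medium)
  list(distribution = dist, peaks = peaks_from_distribution(dist, ...),
       spectrum = spectrum, q = q, beta = attr(g1, "beta"))
}

#' Write a size distribution to delimited text (`rh_nm`, `weight`)
#'
#' @param dist An `scp_size_distribution`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_size_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "scp_size_distribution"))
  utils::write.table(
    data.frame(rh_nm = dist$rh_grid * 1e9, weight = dist$weights),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
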