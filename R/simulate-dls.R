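# Synthetic DLS correlograms: multi-exponential field correlations with
# Rayleigh-regime intensity weighting, folded through the Siegert relation.

#' Intensity autocorrelation container
#'
#' Holds a measured or synthetic g2(t) curve with its lag grid and, when
#' known, the Siegert coherence factor beta.
#'
#' @param lags Strictly increasing positive lag times, seconds.
#' @param g2 Intensity autocorrelation values, same length as `lags`.
#' @param beta Coherence factor in (0, 1], or `NULL` if unknown (it can be
#'   estimated with [estimate_beta()]).
#'
#' @return An object of class `scp_correlation`.
#' @export
correlation_function <- function(lags, g2, beta = NULL) {
  if (!is.numeric(lags) || any(lags <= 0) || any(diff(lags) <= 0)) {
    stop("`lags` must be strictly increasing and positive", call. = FALSE)
  }
  if (length(g2) != length(lags) || any(!is.finite(g2))) {
    stop("`g2` must be finite and match `lags` in length", call. = FALSE)
  }
  if (!is.null(beta) && (beta <= 0 || beta > 1)) {
    stop("`beta` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(lags = as.numeric(lags), g2 = as.numeric(g2), beta = beta),
            class = "scp_correlation")
}

#' @export
print.scp_correlation <- function(x, ...) {
  cat(sprintf("<correlogram> %d lags in [%.2g, %.2g] s, beta = %s\n",
              length(x$lags), min(x$lags), max(x$lags),
              if (is.null(x$beta)) "unknown" else format(x$beta)))
  invisible(x)
}

#' Simulate a DLS intensity autocorrelation curve
#'
#' For spherical populations the field correlation is the intensity-weighted
#' mixture of exponentials g1(t) = sum_i w_i exp(-q^2 D_i t), with Rayleigh
#' weights w_i proportional to `number_density_i * rh_i^6` (normalized to
#' sum 1), and the intensity correlation follows the Siegert relation
#' g2(t) = 1 + beta g1(t)^2, plus additive zero-mean Gaussian noise of
#' standard deviation `noise_sd * beta` per lag.
#'
#' Rod populations are rejected: their rotational-translational coupling is
#' not modeled, mirroring the spherical assumption of the inversion stage.
#'
#' @param modes A single [sphere_population()] or a list of them.
#' @param dls A [dls_acquisition_spec()].
#' @param medium A [medium_conditions()] object.
#' @param seed Optional integer seed (noise reproducibility).
#'
#' @return An `scp_correlation` with a `truth` attribute (data.frame with
#'   per-mode `rh`, `D`, `gamma`, `weight`) recording the generating
#'   mixture.
#' @examples
#' cf <- simulate_dls_g2(sphere_population(100e-9, 1e10),
#'                       dls_acquisition_spec())
#' head(cf$g2)
#' @export
simulate_dls_g2 <- function(modes, dls, medium = medium_conditions(),
                            seed = NULL) {
  if (inherits(modes, "scp_population")) modes <- list(modes)
  if (!length(modes) || !all(vapply(modes, inherits, TRUE, "scp_population"))) {
    stop("`modes` must be one or more population objects", call. = FALSE)
  }
  if (any(vapply(modes, `[[`, "", "shape") == "rod")) {
    stop("rod populations are not supported for DLS synthesis",
         call. = FALSE)
  }
  stopifnot(inherits(dls, "scp_dls_acquisition"))
  .check_medium(medium)
  if (!is.null(seed)) set.seed(seed)

  rh <- vapply(modes, `[[`, 0, "rh")
  dens <- vapply(modes, `[[`, 0, "number_density")
  w <- dens * rh^6
  if (sum(w) <= 0) stop("all intensity weights are zero", call. = FALSE)
  w <- w / sum(w)
  D <- diffusion_coefficient_sphere(rh, medium)
  q <- scattering_vector(medium, dls$wavelength, dls$angle)
  gamma <- q^2 * D

  t <- dls$lag_grid
  g1 <- colSums(w * exp(-outer(gamma, t)))
  g2 <- 1 + dls$beta * g1^2
  if (dls$noise_sd > 0) {
    g2 <- g2 + stats::rnorm(length(t), sd = dls$noise_sd * dls$beta)
  }
  cf <- correlation_function(t, g2, beta = dls$beta)
  attr(cf, "truth") <- data.frame(rh = rh, D = D, gamma = gamma, weight = w)
  cf
}

#' Write a correlogram to delimited text (`lag_s`, `g2`)
#'
#' @param cf An `scp_correlation`.
#' @param path Output file path.
#' @param sep Field separator, tab by default.
#' @return `path`, invisibly.
#' @export
write_correlogram <- function(cf, path, sep = "\t") {
  stopifnot(inherits(cf, "scp_correlation"))
  utils::write.table(data.frame(lag_s = cf$lags, g2 = cf$g2), path,
                     sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a correlogram from delimited text (`lag_s`, `g2`)
#'
#' @param path Input file path (tab- or comma-separated).
#' @param beta Optional known coherence factor to attach.
#' @return An `scp_correlation`.
#' @export
read_correlogram <- function(path, beta = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("lag_s", "g2") %in% names(df))) {
    stop("expected columns: lag_s, g2", call. = FALSE)
  }
  correlation_function(df$lag_s, df$g2, beta = beta)
}
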