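# Per-track mean squared displacement and diffusion-coefficient
# estimators: the core of the nanotracking sizing chain
# MSD -> D -> Stokes-Einstein Rh.

#' Mean squared displacement curve of a track
#'
#' At lag m the MSD is the mean over all overlapping pairs of the squared
#' 2-D displacement between localizations m frames apart. Gap-bridged
#' frames carry no localization and simply contribute no pairs; lags with
#' zero pairs are omitted from the curve.
#'
#' @param track An [new_track()] object.
#' @param max_lag Largest lag (in frames) to evaluate; must be smaller
#'   than the number of localizations.
#' @param frame_interval Frame interval in seconds (converts lags to
#'   times).
#'
#' @return An object of class `scp_msd`: list with `lags` (seconds),
#'   `msd` (m^2) and `n_pairs` per reported lag.
#' @examples
#' tr <- new_track(1, 0:10, (0:10) * 1e-7, rep(0, 11))  # ballistic
#' msd_curve(tr, 2, 0.01)$msd  # (m * 100 nm)^2
#' @export
msd_curve <- function(track, max_lag, frame_interval) {
  stopifnot(inherits(track, "scp_track"))
  max_lag <- as.integer(max_lag)
  if (is.na(max_lag) || max_lag < 1L) stop("`max_lag` must be >= 1",
                                           call. = FALSE)
  n <- length(track$frames)
  if (max_lag >= n) {
    stop("`max_lag` must be smaller than the track length", call. = FALSE)
  }
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("`frame_interval` must be > 0", call. = FALSE)
  }
  lags <- integer(0)
  msd <- numeric(0)
  n_pairs <- integer(0)
  for (m in seq_len(max_lag)) {
    j <- match(track$frames + m, track$frames)
    i <- which(!is.na(j))
    if (!length(i)) next
    j <- j[i]
    d2 <- (track$x[j] - track$x[i])^2 + (track$y[j] - track$y[i])^2
    lags <- c(lags, m)
    msd <- c(msd, mean(d2))
    n_pairs <- c(n_pairs, length(i))
  }
  structure(list(lags = lags * frame_interval, msd = msd,
                 n_pairs = n_pairs),
            class = "scp_msd")
}

#' @export
print.scp_msd <- function(x, ...) {
  cat(sprintf("<MSD curve> %d lags, msd(1) = %.3g m^2 (%d pairs)\n",
              length(x$lags), x$msd[1], x$n_pairs[1]))
  invisible(x)
}

#' Diffusion coefficient from an MSD curve
#'
#' Two estimators for the relation MSD(m dt) = 4 D m dt:
#' \describe{
#'   \item{`lag1`}{D = MSD(dt) / (4 dt). Simple, but static localization
#'     noise inflates the estimate (MSD gains a constant 4 sigma_loc^2).}
#'   \item{`linear_fit`}{D = slope/4 of an unweighted least-squares line
#'     through the first `fit_lags` MSD points with a free intercept; the
#'     intercept absorbs the localization-noise offset.}
#' }
#' Negative estimates (possible for short noisy tracks under
#' `linear_fit`) are returned as-is with `flag = "nonphysical"`; callers
#' decide whether to exclude them.
#'
#' @param curve An [msd_curve()] result.
#' @param mode `"linear_fit"` (default) or `"lag1"`.
#' @param fit_lags Number of leading lags entering the linear fit.
#'
#' @return List with `D` (m^2/s), `se` (standard error, `NA` for `lag1`),
#'   `mode`, and `flag` (`NA` or `"nonphysical"`).
#' @examples
#' tr <- new_track(1, 0:20, cumsum(c(0, rnorm(20, sd = 1e-7))), rep(0, 21))
#' diffusion_from_msd(msd_curve(tr, 4, 0.01))
#' @export
diffusion_from_msd <- function(curve, mode = c("linear_fit", "lag1"),
                               fit_lags = 4L) {
  stopifnot(inherits(curve, "scp_msd"))
  mode <- match.arg(mode)
  if (!length(curve$lags)) stop("empty MSD curve", call. = FALSE)
  if (mode == "lag1") {
    D <- curve$msd[1L] / (4 * curve$lags[1L])
    se <- NA_real_
  } else {
    fit_lags <- as.integer(fit_lags)
    if (fit_lags < 2L) stop("`fit_lags` must be >= 2 for linear_fit",
                            call. = FALSE)
    if (length(curve$lags) < fit_lags) {
      stop("MSD curve has fewer than `fit_lags` points", call. = FALSE)
    }
    t <- curve$lags[seq_len(fit_lags)]
    y <- curve$msd[seq_len(fit_lags)]
    fit <- stats::lm(y ~ t)
    D <- unname(stats::coef(fit)[2L]) / 4
    # slope SE computed directly (avoids summary.lm noise on exact fits)
    sxx <- sum((t - mean(t))^2)
    s2 <- if (fit_lags > 2L) sum(stats::residuals(fit)^2) / (fit_lags - 2L)
      else NA_real_
    se <- if (is.na(s2)) NA_real_ else sqrt(s2 / sxx) / 4
  }
  list(D = D, se = se, mode = mode,
       flag = if (is.finite(D) && D > 0) NA_character_ else "nonphysical")
}
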