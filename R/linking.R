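# Greedy nearest-neighbour track linking. Nanotracking operates in the
# dilute regime where inter-particle spacing far exceeds the per-frame
# step, so distance-gated greedy assignment recovers the true partition;
# no global (LAP/MHT) optimization is attempted.

#' Link per-frame localizations into tracks
#'
#' Frame-by-frame greedy assignment: at each frame, candidate pairs between
#' open tracks (last seen within `max_gap + 1` frames) and current
#' localizations are ranked by distance; pairs are accepted in order of
#' increasing distance (ties broken by smaller track id), subject to the
#' `max_displacement` gate, each localization joining at most one track.
#' Unmatched localizations open new tracks. Gap-bridged frames carry no
#' localization.
#'
#' @param loc Localization data.frame with columns `frame`, `x`, `y`
#'   (meters), as from [read_localizations()]; any `track_id` column is
#'   ignored. Unsorted input is sorted, never rejected.
#' @param max_displacement Maximum frame-to-frame displacement in meters.
#'   The helper [default_max_displacement()] provides a physically
#'   motivated gate.
#' @param max_gap Maximum number of consecutive missed frames a track may
#'   bridge (0 = none).
#' @param acquisition [acquisition_spec()] to attach to the result.
#' @param provenance Free-text origin.
#'
#' @return An `scp_trackset`; singleton localizations (tracks of length 1)
#'   are not represented as tracks but are retained in the per-frame
#'   counts used for number densities.
#' @examples
#' acq <- acquisition_spec(n_frames = 3)
#' loc <- data.frame(frame = c(0, 1, 2), x = c(0, 1e-8, 2e-8), y = 0)
#' link_localizations(loc, 5e-7, acquisition = acq)
#' @export
link_localizations <- function(loc, max_displacement, max_gap = 0L,
                               acquisition = NULL, provenance = "linked") {
  stopifnot(is.data.frame(loc), all(c("frame", "x", "y") %in% names(loc)))
  if (!is.numeric(max_displacement) || max_displacement < 0) {
    stop("`max_displacement` must be >= 0", call. = FALSE)
  }
  max_gap <- as.integer(max_gap)
  if (max_gap < 0L) stop("`max_gap` must be >= 0", call. = FALSE)
  if (is.null(acquisition)) {
    nf <- if (nrow(loc)) max(loc$frame) + 1L else 2L
    acquisition <- acquisition_spec(n_frames = max(nf, 2L))
  }

  # canonical order makes linking invariant to input row order
  loc <- loc[order(loc$frame, loc$x, loc$y), , drop = FALSE]
  assigned <- rep(NA_integer_, nrow(loc))  # track index per localization

  last_x <- numeric(0)
  last_y <- numeric(0)
  last_f <- integer(0)

  for (f in sort(unique(loc$frame))) {
    rows <- which(loc$frame == f)
    open <- which(last_f >= f - 1L - max_gap & last_f < f)
    if (length(open) && length(rows)) {
      dmat <- sqrt(outer(last_x[open], loc$x[rows], `-`)^2 +
                   outer(last_y[open], loc$y[rows], `-`)^2)
      # accept gated candidate pairs in order of increasing distance
      # (ties: smaller/older track index, then input order), each track
      # and localization used at most once -- identical to iterating a
      # global argmin, but one sort instead of repeated matrix scans
      cand <- which(dmat <= max_displacement)
      if (length(cand)) {
        ci <- (cand - 1L) %% length(open) + 1L
        cj <- (cand - 1L) %/% length(open) + 1L
        ord <- order(dmat[cand], ci, cj)
        track_used <- logical(length(open))
        loc_used <- logical(length(rows))
        for (k in ord) {
          if (track_used[ci[k]] || loc_used[cj[k]]) next
          track_used[ci[k]] <- TRUE
          loc_used[cj[k]] <- TRUE
          tr <- open[ci[k]]
          row <- rows[cj[k]]
          assigned[row] <- tr
          last_x[tr] <- loc$x[row]
          last_y[tr] <- loc$y[row]
          last_f[tr] <- f
        }
      }
    }
    for (row in rows[is.na(assigned[rows])]) {
      last_x <- c(last_x, loc$x[row])
      last_y <- c(last_y, loc$y[row])
      last_f <- c(last_f, f)
      assigned[row] <- length(last_x)
    }
  }

  tracks <- list()
  if (nrow(loc)) {
    for (tr in seq_along(last_x)) {
      rows <- which(assigned == tr)
      if (length(rows) >= 2L) {
        tracks[[length(tracks) + 1L]] <-
          new_track(as.character(tr), loc$frame[rows],
                    loc$x[rows], loc$y[rows])
      }
    }
  }
  frame_counts <- tabulate(loc$frame + 1L, nbins = acquisition$n_frames)
  out <- track_set(tracks, acquisition, provenance,
                   frame_counts = as.integer(frame_counts))
  attr(out, "assignment") <- data.frame(
    frame = loc$frame, x = loc$x, y = loc$y, track = assigned)
  out
}

#' Physically motivated linking gate
#'
#' Five times the RMS frame-to-frame 2-D displacement of the largest
#' plausible particle class (i.e. the fastest relevant diffuser sets the
#' scale through the smallest radius): 5 sqrt(4 D dt).
#'
#' @param rh_min Smallest plausible hydrodynamic radius, meters.
#' @param frame_interval Frame interval, seconds.
#' @param medium A [medium_conditions()] object.
#' @return Gate distance in meters.
#' @export
default_max_displacement <- function(rh_min, frame_interval,
                                     medium = medium_conditions()) {
  D <- diffusion_coefficient_sphere(rh_min, medium)
  5 * sqrt(4 * D * frame_interval)
}

#' Drop short tracks
#'
#' @param ts An `scp_trackset`.
#' @param min_length Minimum number of localizations (>= 2).
#' @return The filtered `scp_trackset`; the number of removed tracks is
#'   recorded in the `n_removed` attribute and reported via [message()].
#' @export
filter_tracks <- function(ts, min_length) {
  stopifnot(inherits(ts, "scp_trackset"))
  min_length <- as.integer(min_length)
  if (is.na(min_length) || min_length < 2L) {
    stop("`min_length` must be >= 2", call. = FALSE)
  }
  keep <- vapply(ts$tracks, function(t) length(t$frames) >= min_length, TRUE)
  n_removed <- sum(!keep)
  if (n_removed) message(n_removed, " track(s) below min_length removed")
  out <- track_set(ts$tracks[keep], ts$acquisition, ts$provenance,
                   frame_counts = ts$frame_counts)
  if (!is.null(attr(ts, "truth"))) {
    tr <- attr(ts, "truth")
    ids <- vapply(out$tracks, `[[`, "", "track_id")
    attr(out, "truth") <- tr[tr$track_id %in% ids, , drop = FALSE]
  }
  attr(out, "n_removed") <- n_removed
  out
}
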