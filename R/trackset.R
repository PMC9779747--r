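# Track and TrackSet containers plus the delimited-text dialect used for
# localization/track tables: header `frame, track_id, x_nm, y_nm`, TSV by
# default (comma accepted on read), 0-based frames, nanometer coordinates
# in files, meters internally.

#' Construct a single particle track
#'
#' A track is one particle's time-ordered sequence of 2-D localizations.
#' Frames must be strictly increasing (gaps are allowed and simply carry no
#' localization); positions are in meters.
#'
#' @param track_id Identifier (coerced to character).
#' @param frames Integer frame indices, strictly increasing, 0-based.
#' @param x,y Numeric positions in meters, same length as `frames`.
#'
#' @return An object of class `scp_track`.
#' @examples
#' new_track(1, 0:4, (0:4) * 1e-8, rep(0, 5))
#' @export
new_track <- function(track_id, frames, x, y) {
  frames <- as.integer(frames)
  if (length(frames) < 2L) stop("a track needs >= 2 localizations",
                                call. = FALSE)
  if (any(diff(frames) <= 0L)) stop("`frames` must be strictly increasing",
                                    call. = FALSE)
  if (length(x) != length(frames) || length(y) != length(frames)) {
    stop("`x`, `y` and `frames` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("positions must be finite", call. = FALSE)
  }
  structure(
    list(track_id = as.character(track_id)[1L], frames = frames,
         x = as.numeric(x), y = as.numeric(y)),
    class = "scp_track"
  )
}

#' @export
print.scp_track <- function(x, ...) {
  cat(sprintf("<track %s> %d localizations, frames %d..%d\n",
              x$track_id, length(x$frames), min(x$frames), max(x$frames)))
  invisible(x)
}

#' Construct a set of tracks sharing one acquisition
#'
#' @param tracks List of [new_track()] objects with unique ids.
#' @param acquisition An [acquisition_spec()] shared by all tracks.
#' @param provenance Free-text origin (source file, simulation digest).
#' @param frame_counts Optional integer vector of localizations detected
#'   per frame (length `n_frames`), used for number-density estimation.
#'   When omitted it is tallied from the tracks themselves.
#'
#' @return An object of class `scp_trackset`.
#' @export
track_set <- function(tracks, acquisition, provenance = "",
                      frame_counts = NULL) {
  if (!inherits(acquisition, "scp_acquisition")) {
    stop("`acquisition` must be an acquisition_spec()", call. = FALSE)
  }
  if (!is.list(tracks) ||
      (length(tracks) && !all(vapply(tracks, inherits, TRUE, "scp_track")))) {
    stop("`tracks` must be a list of scp_track objects", call. = FALSE)
  }
  ids <- vapply(tracks, `[[`, "", "track_id")
  if (anyDuplicated(ids)) stop("track ids must be unique", call. = FALSE)
  if (is.null(frame_counts)) {
    frame_counts <- integer(acquisition$n_frames)
    for (tr in tracks) {
      f <- tr$frames + 1L
      f <- f[f >= 1L & f <= acquisition$n_frames]
      frame_counts[f] <- frame_counts[f] + 1L
    }
  }
  structure(
    list(tracks = tracks, acquisition = acquisition,
         provenance = provenance,
         frame_counts = as.integer(frame_counts)),
    class = "scp_trackset"
  )
}

#' @export
print.scp_trackset <- function(x, ...) {
  n <- length(x$tracks)
  if (n) {
    len <- vapply(x$tracks, function(t) length(t$frames), 0L)
    cat(sprintf("<trackset> %d tracks (length %d..%d), %d frames\n",
                n, min(len), max(len), x$acquisition$n_frames))
  } else {
    cat("<trackset> 0 tracks\n")
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.scp_trackset <- function(x) length(x$tracks)

#' Flatten a track set to a localization table
#'
#' @param ts An `scp_trackset`.
#' @return A data.frame with columns `frame`, `track_id`, `x`, `y`
#'   (positions in meters).
#' @export
as_localizations <- function(ts) {
  stopifnot(inherits(ts, "scp_trackset"))
  if (!length(ts$tracks)) {
    return(data.frame(frame = integer(), track_id = character(),
                      x = numeric(), y = numeric()))
  }
  do.call(rbind, lapply(ts$tracks, function(tr) {
    data.frame(frame = tr$frames, track_id = tr$track_id,
               x = tr$x, y = tr$y)
  }))
}

#' Write a track set (or localization table) to delimited text
#'
#' Emits the dialect `frame<TAB>track_id<TAB>x_nm<TAB>y_nm`; coordinates
#' are converted from meters to nanometers. An unlinked localization table
#' (data.frame with `frame`, `x`, `y` and optionally `track_id`) is also
#' accepted; a missing `track_id` is written empty.
#'
#' @param x An `scp_trackset` or a localization data.frame (meters).
#' @param path Output file path.
#' @param sep Field separator, tab by default.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(x, path, sep = "\t") {
  if (inherits(x, "scp_trackset")) x <- as_localizations(x)
  stopifnot(is.data.frame(x), all(c("frame", "x", "y") %in% names(x)))
  out <- data.frame(
    frame = as.integer(x$frame),
    track_id = if ("track_id" %in% names(x)) as.character(x$track_id) else "",
    x_nm = x$x * 1e9,
    y_nm = x$y * 1e9
  )
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a localization/track table from delimited text
#'
#' Accepts tab- or comma-separated files with header
#' `frame, track_id, x_nm, y_nm` (`track_id` may be empty for unlinked
#' localizations). Coordinates are converted to meters.
#'
#' @param path Input file path.
#' @return A data.frame with columns `frame`, `track_id` (character, `NA`
#'   where empty), `x`, `y` in meters.
#' @export
read_localizations <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = c("integer", "character",
                                         "numeric", "numeric"),
                          na.strings = c("", "NA"))
  need <- c("frame", "track_id", "x_nm", "y_nm")
  if (!all(need %in% names(df))) {
    stop("expected columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  data.frame(frame = df$frame, track_id = df$track_id,
             x = df$x_nm * 1e-9, y = df$y_nm * 1e-9)
}

#' Assemble a track set from a linked localization table
#'
#' Groups a localization data.frame (meters, with non-missing `track_id`)
#' into tracks; rows with missing ids and singleton groups are dropped.
#'
#' @param loc Localization data.frame as returned by
#'   [read_localizations()].
#' @param acquisition The [acquisition_spec()] under which the
#'   localizations were recorded.
#' @param provenance Free-text origin.
#' @return An `scp_trackset`. Per-frame counts include every input
#'   localization (linked or not), so number densities are unaffected by
#'   singleton removal.
#' @export
as_track_set <- function(loc, acquisition, provenance = "") {
  stopifnot(is.data.frame(loc), all(c("frame", "x", "y") %in% names(loc)))
  frame_counts <- integer(acquisition$n_frames)
  f <- loc$frame + 1L
  f <- f[f >= 1L & f <= acquisition$n_frames]
  tab <- tabulate(f, nbins = acquisition$n_frames)
  frame_counts <- as.integer(tab)
  keep <- !is.na(loc$track_id)
  loc <- loc[keep, , drop = FALSE]
  tracks <- list()
  if (nrow(loc)) {
    for (id in unique(loc$track_id)) {
      g <- loc[loc$track_id == id, , drop = FALSE]
      g <- g[order(g$frame), , drop = FALSE]
      if (nrow(g) >= 2L) {
        tracks[[length(tracks) + 1L]] <- new_track(id, g$frame, g$x, g$y)
      }
    }
  }
  track_set(tracks, acquisition, provenance, frame_counts)
}
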