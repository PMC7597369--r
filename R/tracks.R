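#' Build track objects from a localization table with known track ids
#'
#' Groups a track table (e.g. from [emit_tracks()], [read_tracks()], or a
#' deposited trajectory table) by `track_id` and channel into per-track
#' summaries: start/end times, duration, time-averaged position, and
#' censoring flags. Use [link_tracks()] instead when localizations carry
#' no track identity yet.
#'
#' The duration convention is `(n_frames_spanned) * frame_interval`,
#' counting bridged gap frames, so the minimum observable duration is one
#' frame interval. Tracks touching the first or last movie frame are
#' flagged censored; censored tracks should be excluded from residence-time
#' fitting but are retained for maps and colocalization.
#'
#' @param locs A track-table data frame (columns `track_id`, `channel`,
#'   `frame`, `t_s`, `x_nm`, `y_nm`, and optionally `intensity`).
#' @param frame_interval_s Per-channel frame interval (s).
#' @param n_frames Number of frames per channel in the movie (used for the
#'   end-censoring flag); `NULL` infers `max(frame) + 1`.
#' @return An object of class `smt_tracks`: a data frame with one row per
#'   track (`track_id`, `channel`, `start_t`, `end_t`, `duration_s`,
#'   `mean_x`, `mean_y`, `n_locs`, `censored_start`, `censored_end`) and
#'   the localization table attached as attribute `locs`.
#' @examples
#' cfg <- sim_config(n_events_per_channel = 50, seed = 4)
#' tab <- emit_tracks(generate_truth(cfg), cfg)
#' trk <- tracks_from_table(tab, cfg$frame_interval_s, cfg$movie_length_frames)
#' head(trk)
#' @export
tracks_from_table <- function(locs, frame_interval_s = 1.34, n_frames = NULL) {
  if (nrow(locs) == 0L) return(empty_tracks(locs, frame_interval_s))
  if (is.null(n_frames)) n_frames <- max(locs$frame) + 1L
  key <- paste(locs$channel, locs$track_id, sep = "\r")
  first <- !duplicated(key)
  agg <- function(v, f) as.numeric(tapply(v, key, f)[unique(key)])
  ids <- locs$track_id[first]
  ch <- locs$channel[first]
  out <- data.frame(
    track_id = ids, channel = ch,
    start_t = agg(locs$t_s, min), end_t = agg(locs$t_s, max),
    fmin = agg(locs$frame, min), fmax = agg(locs$frame, max),
    mean_x = agg(locs$x_nm, mean), mean_y = agg(locs$y_nm, mean),
    n_locs = agg(locs$t_s, length), stringsAsFactors = FALSE)
  out$duration_s <- (out$fmax - out$fmin + 1) * frame_interval_s
  out$censored_start <- out$fmin == 0L
  out$censored_end <- out$fmax == n_frames - 1L
  out <- out[, c("track_id", "channel", "start_t", "end_t", "duration_s",
                 "mean_x", "mean_y", "n_locs",
                 "censored_start", "censored_end")]
  rownames(out) <- NULL
  new_tracks(out, locs, frame_interval_s)
}

new_tracks <- function(summary, locs, frame_interval_s) {
  attr(summary, "locs") <- as.data.frame(locs)
  attr(summary, "frame_interval_s") <- frame_interval_s
  attr(summary, "pixel_size_nm") <- attr(locs, "pixel_size_nm")
  class(summary) <- c("smt_tracks", "data.frame")
  summary
}

empty_tracks <- function(locs, frame_interval_s) {
  out <- data.frame(track_id = integer(0), channel = character(0),
                    start_t = numeric(0), end_t = numeric(0),
                    duration_s = numeric(0), mean_x = numeric(0),
                    mean_y = numeric(0), n_locs = integer(0),
                    censored_start = logical(0), censored_end = logical(0))
  new_tracks(out, locs, frame_interval_s)
}

#' Localizations belonging to a track object
#'
#' @param tracks An `smt_tracks` object.
#' @return The localization table attached to `tracks`.
#' @export
track_locs <- function(tracks) attr(tracks, "locs")

#' @export
print.smt_tracks <- function(x, ...) {
  cat(sprintf("%d tracks (%s); frame interval %.2f s\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$channel)),
                            as.integer(table(x$channel))), collapse = ", "),
              attr(x, "frame_interval_s")))
  NextMethod()
}

#' Subset tracks by channel
#'
#' @param tracks An `smt_tracks` object.
#' @param channel `"pold"` or `"pcna"`.
#' @return An `smt_tracks` object restricted to one channel (its
#'   localization table is filtered accordingly).
#' @export
channel_tracks <- function(tracks, channel) {
  check_channel(channel)
  keep <- tracks$channel == channel
  locs <- track_locs(tracks)
  sub <- as.data.frame(tracks)[keep, , drop = FALSE]
  rownames(sub) <- NULL
  new_tracks(sub, locs[locs$channel == channel, , drop = FALSE],
             attr(tracks, "frame_interval_s"))
}

#' Uncensored residence times of a track set
#'
#' Convenience extractor for survival analysis: durations of tracks not
#' censored by the movie start or end.
#'
#' @param tracks An `smt_tracks` object.
#' @param channel Optional channel filter.
#' @return Numeric vector of durations (s).
#' @export
residence_times <- function(tracks, channel = NULL) {
  x <- as.data.frame(tracks)
  if (!is.null(channel)) x <- x[x$channel == channel, , drop = FALSE]
  x$duration_s[!(x$censored_start | x$censored_end)]
}
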