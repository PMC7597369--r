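#' Link localizations into tracks by diffusion-gated optimal assignment
#'
#' Connects single-channel localizations between frames into binding-event
#' tracks. At each frame, open track heads compete for the new
#' localizations through an optimal weighted bipartite assignment
#' (cardinality first, then minimum total squared displacement), gated by
#' the diffusion radius `r_max(dt) = sqrt(4 * d_max * dt)` where `dt` is
#' the elapsed time since the head's last localization. A track may bridge
#' missing frames as long as the bridged gap (missing frames times the
#' frame interval) does not exceed `max_gap_s`, accommodating blinking and
#' missed localizations; heads older than that are closed.
#'
#' @param locs Data frame of localizations for one channel, with columns
#'   `frame` (0-based), `t_s`, `x_nm`, `y_nm`, and optionally `intensity`
#'   and `channel` (must be a single channel).
#' @param d_max_um2_s Maximum expected diffusion constant (um^2/s) of a
#'   bound molecule; sets the gating radius.
#' @param max_gap_s Maximum bridged gap (s).
#' @param frame_interval_s Per-channel frame interval (s).
#' @param n_frames Frames per channel (for censoring flags); `NULL` infers
#'   `max(frame) + 1`.
#' @return An `smt_tracks` object (see [tracks_from_table()]); assigned
#'   track ids are recorded in the attached localization table.
#' @examples
#' locs <- data.frame(channel = "pold", frame = 0:4, t_s = (0:4) * 1.34,
#'                    x_nm = 500 + rnorm(5, 0, 10), y_nm = 800, intensity = 1)
#' link_tracks(locs)
#' @export
link_tracks <- function(locs, d_max_um2_s = 0.05, max_gap_s = 5,
                        frame_interval_s = 1.34, n_frames = NULL) {
  if (nrow(locs) == 0L) {
    locs$track_id <- integer(0)
    return(empty_tracks(locs, frame_interval_s))
  }
  if (!is.null(locs$channel) && length(unique(locs$channel)) > 1L)
    stopf("link_tracks expects a single channel; split by channel first")
  if (is.unsorted(locs$frame)) locs <- locs[order(locs$frame), , drop = FALSE]
  d_nm2 <- d_max_um2_s * 1e6  # nm^2/s
  frames <- sort(unique(locs$frame))
  idx_by_frame <- split(seq_len(nrow(locs)), locs$frame)
  track_id <- integer(nrow(locs))
  # open heads: row index of last localization, per live track
  head_row <- integer(0)
  head_track <- integer(0)
  next_id <- 1L
  for (f in as.character(frames)) {
    rows <- idx_by_frame[[f]]
    fnum <- locs$frame[rows[1]]
    tnow <- locs$t_s[rows[1]]
    if (length(head_row)) {
      gap_frames <- fnum - locs$frame[head_row] - 1L
      open <- gap_frames * frame_interval_s <= max_gap_s
      head_row <- head_row[open]
      head_track <- head_track[open]
    }
    if (length(head_row)) {
      dt <- tnow - locs$t_s[head_row]
      r_gate <- sqrt(4 * d_nm2 * dt)
      dx <- outer(locs$x_nm[head_row], locs$x_nm[rows], "-")
      dy <- outer(locs$y_nm[head_row], locs$y_nm[rows], "-")
      d2 <- dx * dx + dy * dy
      admissible <- d2 <= r_gate^2
      assign_to <- gated_assignment(d2, admissible)
      matched_new <- !is.na(assign_to)
      for (j in which(matched_new)) {
        hi <- assign_to[j]
        track_id[rows[j]] <- head_track[hi]
        head_row[hi] <- rows[j]
      }
      new_rows <- rows[!matched_new]
    } else new_rows <- rows
    if (length(new_rows)) {
      ids <- seq.int(next_id, next_id + length(new_rows) - 1L)
      track_id[new_rows] <- ids
      next_id <- next_id + length(new_rows)
      head_row <- c(head_row, new_rows)
      head_track <- c(head_track, ids)
    }
  }
  locs$track_id <- track_id
  tracks_from_table(locs, frame_interval_s, n_frames)
}

# Optimal bipartite assignment of columns (new localizations) to rows
# (track heads) under an admissibility gate, maximizing the number of
# matches and, among maximum matchings, minimizing total squared
# displacement. Returns, per column, the matched row index or NA.
gated_assignment <- function(d2, admissible) {
  nr <- nrow(d2); nc <- ncol(d2)
  out <- rep(NA_integer_, nc)
  ij <- which(admissible, arr.ind = TRUE)
  if (nrow(ij) == 0L) return(out)
  # weight = BIG - d2 > 0; BIG large enough that cardinality dominates
  big <- max(d2[admissible]) * (min(nr, nc) + 1) + 1
  w <- big - d2[admissible]
  edges <- rbind(ij[, 1], nr + ij[, 2])
  g <- igraph::make_bipartite_graph(c(rep(FALSE, nr), rep(TRUE, nc)),
                                    as.vector(edges))
  m <- igraph::max_bipartite_match(g, weights = w)$matching
  for (col in seq_len(nc)) {
    r <- m[nr + col]
    if (!is.na(r)) out[col] <- as.integer(r)
  }
  out
}
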