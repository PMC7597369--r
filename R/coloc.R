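#' Detect polymerase-clamp colocalization events
#'
#' Pairs polymerase (Pol delta) tracks with clamp (PCNA) tracks that are
#' bound at the same place and time. A polymerase track qualifies only if
#' its duration strictly exceeds `min_pold_s`. A candidate pair is an
#' event when the two bound intervals overlap in time (closed intervals on
#' the interleaved clock; boundary touching counts) and the distance
#' between the tracks' time-averaged positions over the overlap window is
#' strictly below `radius_nm`. Each polymerase track pairs with at most
#' one clamp track: the nearest by separation, ties broken by the longer
#' temporal overlap.
#'
#' With `method = "perframe"` the distance criterion instead uses the
#' minimum frame-pair distance within the overlap window.
#'
#' @param pold_tracks,pcna_tracks `smt_tracks` objects for the two
#'   channels of one nucleus, in a shared coordinate frame.
#' @param radius_nm Colocalization radius (nm).
#' @param min_pold_s Minimum polymerase track duration (s, strict).
#' @param method Distance criterion: time-averaged positions over the
#'   overlap window (default) or per-frame minimum.
#' @param simultaneity_tol_s Tolerance (s) below which arrival or
#'   departure time differences are classed simultaneous.
#' @return A data frame of class `coloc_events`: `event_id`, `pold_track`,
#'   `pcna_track`, `sep_nm`, `coloc_start_t`, `coloc_end_t`, `coloc_s`,
#'   `pre_s`, `post_s`, `pold_start`, `pold_end`, `pcna_start`,
#'   `pcna_end`, `arrival`, `departure`. `pre_s`/`post_s` are the
#'   partner-alone times before/after joint binding; `coloc_s` is
#'   `coloc_end_t - coloc_start_t`.
#' @export
detect_colocalizations <- function(pold_tracks, pcna_tracks, radius_nm = 47,
                                   min_pold_s = 1.34,
                                   method = c("mean", "perframe"),
                                   simultaneity_tol_s = NULL) {
  method <- match.arg(method)
  px1 <- attr(pold_tracks, "pixel_size_nm")
  px2 <- attr(pcna_tracks, "pixel_size_nm")
  if (!is.null(px1) && !is.null(px2) && !isTRUE(all.equal(px1, px2)))
    stopf("mismatched coordinate frames: pixel sizes %.3g and %.3g nm",
          px1, px2)
  dt <- attr(pold_tracks, "frame_interval_s") %||% 1.34
  if (is.null(simultaneity_tol_s)) simultaneity_tol_s <- dt
  p <- as.data.frame(pold_tracks)
  q <- as.data.frame(pcna_tracks)
  p <- p[p$duration_s > min_pold_s, , drop = FALSE]
  empty <- empty_coloc_events()
  attr(empty, "radius_nm") <- radius_nm
  attr(empty, "min_pold_s") <- min_pold_s
  attr(empty, "n_pold_qualifying") <- nrow(p)
  if (nrow(p) == 0L || nrow(q) == 0L) return(empty)
  plocs <- track_locs(pold_tracks)
  qlocs <- track_locs(pcna_tracks)
  pbb <- track_bboxes(p, plocs)
  qbb <- track_bboxes(q, qlocs)
  ## candidate pairs: temporal overlap (closed) and bbox gap <= radius
  ov <- outer(p$start_t, q$end_t, "<=") &
    t(outer(q$start_t, p$end_t, "<="))
  gx <- pmax(outer(pbb$xmin, qbb$xmax, "-"),
             t(outer(qbb$xmin, pbb$xmax, "-")), 0)
  gy <- pmax(outer(pbb$ymin, qbb$ymax, "-"),
             t(outer(qbb$ymin, pbb$ymax, "-")), 0)
  cand <- which(ov & (gx * gx + gy * gy <= radius_nm^2), arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  psplit <- split(plocs, plocs$track_id)
  qsplit <- split(qlocs, qlocs$track_id)
  sep <- numeric(nrow(cand)); olen <- numeric(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    t0 <- max(p$start_t[i], q$start_t[j])
    t1 <- min(p$end_t[i], q$end_t[j])
    li <- psplit[[as.character(p$track_id[i])]]
    lj <- qsplit[[as.character(q$track_id[j])]]
    sep[r] <- pair_separation(li, lj, t0, t1, dt, method)
    olen[r] <- t1 - t0
  }
  hit <- sep < radius_nm
  cand <- cand[hit, , drop = FALSE]
  sep <- sep[hit]; olen <- olen[hit]
  if (nrow(cand) == 0L) return(empty)
  ## one-to-one from the polymerase side: nearest, ties by longer overlap
  keep <- rep(FALSE, nrow(cand))
  for (i in unique(cand[, 1])) {
    rows <- which(cand[, 1] == i)
    best <- rows[order(sep[rows], -olen[rows])][1]
    keep[best] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  sep <- sep[keep]
  i <- cand[, 1]; j <- cand[, 2]
  t0 <- pmax(p$start_t[i], q$start_t[j])
  t1 <- pmin(p$end_t[i], q$end_t[j])
  out <- data.frame(
    event_id = seq_along(i),
    pold_track = p$track_id[i], pcna_track = q$track_id[j],
    sep_nm = sep, coloc_start_t = t0, coloc_end_t = t1,
    coloc_s = t1 - t0,
    pre_s = t0 - pmin(p$start_t[i], q$start_t[j]),
    post_s = pmax(p$end_t[i], q$end_t[j]) - t1,
    pold_start = p$start_t[i], pold_end = p$end_t[i],
    pcna_start = q$start_t[j], pcna_end = q$end_t[j])
  out <- classify_order(out, simultaneity_tol_s)
  class(out) <- c("coloc_events", "data.frame")
  attr(out, "radius_nm") <- radius_nm
  attr(out, "min_pold_s") <- min_pold_s
  attr(out, "n_pold_qualifying") <- nrow(p)
  out
}

empty_coloc_events <- function() {
  out <- data.frame(event_id = integer(0), pold_track = integer(0),
                    pcna_track = integer(0), sep_nm = numeric(0),
                    coloc_start_t = numeric(0), coloc_end_t = numeric(0),
                    coloc_s = numeric(0), pre_s = numeric(0),
                    post_s = numeric(0), pold_start = numeric(0),
                    pold_end = numeric(0), pcna_start = numeric(0),
                    pcna_end = numeric(0), arrival = character(0),
                    departure = character(0))
  class(out) <- c("coloc_events", "data.frame")
  attr(out, "n_pold_qualifying") <- 0L
  out
}

track_bboxes <- function(tracks, locs) {
  key <- match(locs$track_id, tracks$track_id)
  ok <- !is.na(key)
  agg <- function(v, f, init) {
    out <- rep(init, nrow(tracks))
    t <- tapply(v[ok], key[ok], f)
    out[as.integer(names(t))] <- as.numeric(t)
    out
  }
  list(xmin = agg(locs$x_nm, min, Inf), xmax = agg(locs$x_nm, max, -Inf),
       ymin = agg(locs$y_nm, min, Inf), ymax = agg(locs$y_nm, max, -Inf))
}

# Distance between two tracks over the temporal overlap window [t0, t1].
# "mean": distance of the two within-window time-averaged positions;
# if the interleaved grids leave one track without localizations inside
# the closed window, the window is widened by half a frame interval.
# "perframe": minimum distance over all localization pairs within the
# (widened, for grid phase) window whose times differ by <= dt.
pair_separation <- function(li, lj, t0, t1, dt, method) {
  sel_i <- li$t_s >= t0 & li$t_s <= t1
  sel_j <- lj$t_s >= t0 & lj$t_s <= t1
  if (!any(sel_i)) sel_i <- li$t_s >= t0 - dt / 2 & li$t_s <= t1 + dt / 2
  if (!any(sel_j)) sel_j <- lj$t_s >= t0 - dt / 2 & lj$t_s <= t1 + dt / 2
  if (!any(sel_i) || !any(sel_j)) return(Inf)
  if (method == "mean") {
    sqrt((mean(li$x_nm[sel_i]) - mean(lj$x_nm[sel_j]))^2 +
           (mean(li$y_nm[sel_i]) - mean(lj$y_nm[sel_j]))^2)
  } else {
    xi <- li$x_nm[sel_i]; yi <- li$y_nm[sel_i]; ti <- li$t_s[sel_i]
    xj <- lj$x_nm[sel_j]; yj <- lj$y_nm[sel_j]; tj <- lj$t_s[sel_j]
    near <- abs(outer(ti, tj, "-")) <= dt
    if (!any(near)) return(Inf)
    d2 <- outer(xi, xj, "-")^2 + outer(yi, yj, "-")^2
    sqrt(min(d2[near]))
  }
}

#' Classify arrival and departure order of colocalization events
#'
#' Applies the simultaneity tolerance independently to arrivals and
#' departures: when the absolute start-time (end-time) difference is
#' within `tol_s` the class is `"simultaneous"`; otherwise the sign
#' decides which molecule arrived (departed) first. Because the two
#' channels are never exposed at the same instant, the default tolerance
#' of one per-channel frame interval is the finest resolvable ordering.
#'
#' @param events A `coloc_events` data frame (or any data frame with
#'   `pold_start`, `pold_end`, `pcna_start`, `pcna_end`).
#' @param tol_s Simultaneity tolerance (s).
#' @return `events` with `arrival` (one of `pcna_first`, `pold_first`,
#'   `simultaneous`) and `departure` (one of `pold_first`, `pcna_first`,
#'   `simultaneous`) columns set.
#' @export
classify_order <- function(events, tol_s = 1.34) {
  da <- events$pold_start - events$pcna_start   # > 0: clamp arrived first
  dd <- events$pcna_end - events$pold_end       # > 0: polymerase left first
  events$arrival <- ifelse(abs(da) <= tol_s, "simultaneous",
                           ifelse(da > 0, "pcna_first", "pold_first"))
  events$departure <- ifelse(abs(dd) <= tol_s, "simultaneous",
                             ifelse(dd > 0, "pold_first", "pcna_first"))
  events
}

#' Colocalization frequency
#'
#' Percentage of qualifying polymerase tracks that colocalize with a
#' clamp track.
#'
#' @param events A `coloc_events` data frame.
#' @param n_pold_tracks Number of qualifying (duration-filtered)
#'   polymerase tracks; defaults to the count recorded by
#'   [detect_colocalizations()].
#' @return Percent (0-100).
#' @export
colocalization_frequency <- function(events,
                                     n_pold_tracks =
                                       attr(events, "n_pold_qualifying")) {
  if (is.null(n_pold_tracks) || !is_count(n_pold_tracks) ||
      n_pold_tracks < 1)
    stopf("n_pold_tracks must be a positive count")
  100 * nrow(events) / n_pold_tracks
}
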