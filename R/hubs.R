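#' The pinned 20-pixel octagon window kernel
#'
#' The raster-scan window used for hub detection is a regular octagon of
#' 168 nm diameter, i.e. 20 expanded (8.4 nm) pixels. "Octagon" admits
#' several rasterizations, so one is pinned bit-exactly: a 20 x 20 square
#' with 45-degree corner cuts of 6 pixels (offsets `dx, dy` in -10..9;
#' with `u = dx + 10`, `v = dy + 10` a pixel belongs to the window iff
#' `u + v >= 6`, `u + v <= 32`, and `|u - v| <= 13`). The same matrix is
#' shipped as a text fixture in `inst/extdata/octagon_kernel_20.txt`.
#'
#' @param diameter_px Window diameter in expanded pixels (must be 20 for
#'   the shipped rasterization; other even diameters use the same
#'   `round(d / (2 + sqrt(2)))` corner-cut rule).
#' @return A logical `diameter_px` x `diameter_px` matrix; attribute
#'   `offsets` holds the integer offset pairs (dx, dy) of member pixels
#'   relative to the window center pixel.
#' @examples
#' k <- octagon_kernel()
#' sum(k)  # 316 member pixels
#' @export
octagon_kernel <- function(diameter_px = 20L) {
  d <- as.integer(diameter_px)
  if (d < 4L || d %% 2L != 0L) stopf("diameter must be an even count >= 4")
  cut <- round(d / (2 + sqrt(2)))
  u <- matrix(0:(d - 1L), d, d)
  v <- t(u)
  k <- (u + v >= cut) & (u + v <= 2L * (d - 1L) - cut) & (abs(u - v) <= d - 1L - cut)
  half <- d %/% 2L
  ij <- which(k, arr.ind = TRUE)
  attr(k, "offsets") <- cbind(dx = ij[, 1] - 1L - half,
                              dy = ij[, 2] - 1L - half)
  k
}

#' Expand binding events onto the high-resolution hub-detection grid
#'
#' Bins track mean positions onto a grid expanded `factor`-fold relative
#' to the native camera pixels (8.4 nm at the defaults). By default only
#' long-lived events (duration > 1.7 s, the stable T2 class) enter the
#' map.
#'
#' @param tracks An `smt_tracks` object (or data frame with `track_id`,
#'   `mean_x`, `mean_y`, `start_t`, `end_t`, `duration_s`).
#' @param factor Expansion factor.
#' @param pixel_size_nm Native pixel size (nm).
#' @param field_size_px Native field size `c(nx, ny)`.
#' @param min_duration_s Only events strictly longer than this enter the
#'   map; `0` keeps everything.
#' @return An object of class `event_map`: list with `events` (data frame
#'   `track_id`, `ix`, `iy` 0-based expanded-grid pixels, `x_nm`, `y_nm`,
#'   `start_t`, `end_t`), `dims` (expanded grid size), `pixel_size_nm`
#'   (expanded), `factor`.
#' @export
expand_map <- function(tracks, factor = 10L, pixel_size_nm = 84,
                       field_size_px = c(512L, 512L), min_duration_s = 1.7) {
  x <- as.data.frame(tracks)
  if (!is.null(x$duration_s) && min_duration_s > 0)
    x <- x[x$duration_s > min_duration_s, , drop = FALSE]
  exp_px <- pixel_size_nm / factor
  ev <- data.frame(
    track_id = x$track_id %||% seq_len(nrow(x)),
    ix = as.integer(floor(x$mean_x / exp_px)),
    iy = as.integer(floor(x$mean_y / exp_px)),
    x_nm = x$mean_x, y_nm = x$mean_y,
    start_t = x$start_t %||% rep(NA_real_, nrow(x)),
    end_t = x$end_t %||% rep(NA_real_, nrow(x)))
  structure(list(events = ev,
                 dims = as.integer(field_size_px) * as.integer(factor),
                 pixel_size_nm = exp_px, factor = as.integer(factor)),
            class = "event_map")
}

#' @export
print.event_map <- function(x, ...) {
  cat(sprintf("Event map: %d events on a %d x %d grid (%.2f nm/px)\n",
              nrow(x$events), x$dims[1], x$dims[2], x$pixel_size_nm))
  invisible(x)
}

#' Raster-scan the octagon window over an event map
#'
#' Counts, for every expanded-grid pixel, the binding events inside the
#' octagon window centered there, and marks pixels whose count reaches
#' `min_events` as hub seeds. Equivalent to raster scanning the window
#' across the whole map, implemented by stamping the reflected kernel at
#' each event (exact integer counts; identical to the naive per-pixel
#' scan).
#'
#' @param map An `event_map` from [expand_map()].
#' @param diameter_nm Window diameter (nm); must be an even multiple of
#'   the expanded pixel size.
#' @param min_events Events required in a window (>= this count).
#' @return An object of class `hub_mask`: list with `pixels` (data frame
#'   `ix`, `iy`, `count` for every pixel with a nonzero window count),
#'   `seed` (logical vector flagging `count >= min_events`), `min_events`,
#'   `kernel`, `dims`, `map`.
#' @export
scan_octagon <- function(map, diameter_nm = 168, min_events = 3L) {
  stopifnot(inherits(map, "event_map"))
  d_px <- diameter_nm / map$pixel_size_nm
  if (abs(d_px - round(d_px)) > 1e-9)
    stopf("window diameter (%.3g nm) is not a multiple of the pixel size (%.3g nm)",
          diameter_nm, map$pixel_size_nm)
  kernel <- octagon_kernel(as.integer(round(d_px)))
  off <- attr(kernel, "offsets")
  ev <- map$events
  if (nrow(ev) == 0L)
    return(structure(list(pixels = data.frame(ix = integer(0),
                                              iy = integer(0),
                                              count = integer(0)),
                          seed = logical(0), min_events = min_events,
                          kernel = kernel, dims = map$dims, map = map),
                     class = "hub_mask"))
  # window at p contains event q iff (q - p) is a kernel offset, so each
  # event q contributes to pixels p = q - offset
  px <- rep(ev$ix, each = nrow(off)) - rep(off[, "dx"], times = nrow(ev))
  py <- rep(ev$iy, each = nrow(off)) - rep(off[, "dy"], times = nrow(ev))
  ok <- px >= 0L & px < map$dims[1] & py >= 0L & py < map$dims[2]
  key <- px[ok] + as.numeric(map$dims[1]) * py[ok]
  tab <- table(key)
  keys <- as.numeric(names(tab))
  pixels <- data.frame(ix = as.integer(keys %% map$dims[1]),
                       iy = as.integer(keys %/% map$dims[1]),
                       count = as.integer(tab))
  structure(list(pixels = pixels, seed = pixels$count >= min_events,
                 min_events = as.integer(min_events), kernel = kernel,
                 dims = map$dims, map = map),
            class = "hub_mask")
}

#' @export
print.hub_mask <- function(x, ...) {
  cat(sprintf("Hub mask: %d pixels with events in window, %d seed pixels (>= %d events)\n",
              nrow(x$pixels), sum(x$seed), x$min_events))
  invisible(x)
}

#' Label contiguous hub-seed regions as hubs
#'
#' Connected components (8-connectivity by default) of the hub-seed mask
#' become hubs. An event belongs to a hub when its position falls inside
#' any octagon window centered on one of the component's pixels; the rare
#' event reachable from two hubs is assigned to the nearer centroid.
#' Hubs are ordered by centroid for determinism.
#'
#' @param mask A `hub_mask` from [scan_octagon()].
#' @param connectivity 8 (default) or 4.
#' @return An object of class `hub_set`: list with `hubs` (data frame
#'   `hub_id`, `n_events`, `centroid_x_nm`, `centroid_y_nm`, `n_pixels`)
#'   and `members` (list of per-hub event data frames, ordered by start
#'   time).
#' @export
label_hubs <- function(mask, connectivity = 8L) {
  stopifnot(inherits(mask, "hub_mask"))
  seeds <- mask$pixels[mask$seed, , drop = FALSE]
  if (nrow(seeds) == 0L)
    return(structure(list(hubs = empty_hub_table(), members = list()),
                     class = "hub_set"))
  lab <- pixel_components(seeds$ix, seeds$iy, mask$dims[1], connectivity)
  ## event membership: event q is covered by a component pixel p when
  ## (q - p) is a kernel offset
  ev <- mask$map$events
  off <- attr(mask$kernel, "offsets")
  seed_key <- seeds$ix + as.numeric(mask$dims[1]) * seeds$iy
  lab_by_key <- lab
  names(lab_by_key) <- as.character(seed_key)
  n_comp <- max(lab)
  memb_rows <- vector("list", n_comp)
  assign_comp <- rep(NA_integer_, nrow(ev))
  cand_comps <- vector("list", nrow(ev))
  for (e in seq_len(nrow(ev))) {
    pk <- (ev$ix[e] - off[, "dx"]) + as.numeric(mask$dims[1]) *
      (ev$iy[e] - off[, "dy"])
    comps <- unique(lab_by_key[as.character(pk)])
    comps <- comps[!is.na(comps)]
    cand_comps[[e]] <- comps
    if (length(comps) == 1L) assign_comp[e] <- comps
  }
  # provisional centroids from unambiguous members resolve ties
  cx <- tapply(ev$x_nm, assign_comp, mean)
  cy <- tapply(ev$y_nm, assign_comp, mean)
  for (e in which(is.na(assign_comp) & lengths(cand_comps) > 1L)) {
    comps <- cand_comps[[e]]
    d2 <- (as.numeric(cx[as.character(comps)]) - ev$x_nm[e])^2 +
      (as.numeric(cy[as.character(comps)]) - ev$y_nm[e])^2
    d2[is.na(d2)] <- Inf
    assign_comp[e] <- comps[which.min(d2)]
  }
  hubs <- list(); members <- list()
  for (c_id in seq_len(n_comp)) {
    rows <- ev[which(assign_comp == c_id), , drop = FALSE]
    if (nrow(rows) == 0L) next
    rows <- rows[order(rows$start_t), , drop = FALSE]
    hubs[[length(hubs) + 1L]] <- data.frame(
      n_events = nrow(rows),
      centroid_x_nm = mean(rows$x_nm), centroid_y_nm = mean(rows$y_nm),
      n_pixels = sum(lab == c_id))
    members[[length(members) + 1L]] <- rows
  }
  if (!length(hubs))
    return(structure(list(hubs = empty_hub_table(), members = list()),
                     class = "hub_set"))
  hubs <- do.call(rbind, hubs)
  ord <- order(hubs$centroid_x_nm, hubs$centroid_y_nm)
  hubs <- hubs[ord, , drop = FALSE]
  members <- members[ord]
  hubs <- cbind(hub_id = seq_len(nrow(hubs)), hubs)
  rownames(hubs) <- NULL
  structure(list(hubs = hubs, members = members), class = "hub_set")
}

empty_hub_table <- function() {
  data.frame(hub_id = integer(0), n_events = integer(0),
             centroid_x_nm = numeric(0), centroid_y_nm = numeric(0),
             n_pixels = integer(0))
}

# Connected components of a sparse pixel set via igraph.
pixel_components <- function(ix, iy, nx, connectivity = 8L) {
  key <- ix + as.numeric(nx + 2L) * iy   # pad to avoid wraparound joins
  idx <- seq_along(key)
  names(idx) <- as.character(key)
  neigh <- if (connectivity == 8L)
    cbind(dx = c(1L, 0L, 1L, -1L), dy = c(0L, 1L, 1L, 1L))
  else cbind(dx = c(1L, 0L), dy = c(0L, 1L))
  edges <- integer(0)
  for (r in seq_len(nrow(neigh))) {
    nk <- (ix + neigh[r, "dx"]) + as.numeric(nx + 2L) * (iy + neigh[r, "dy"])
    j <- idx[as.character(nk)]
    ok <- !is.na(j)
    if (any(ok)) edges <- c(edges, rbind(idx[ok], j[ok]))
  }
  g <- igraph::make_empty_graph(length(key), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$membership
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("%d hubs; events per hub: %s\n", nrow(x$hubs),
              if (nrow(x$hubs)) paste(x$hubs$n_events, collapse = ", ")
              else "-"))
  invisible(x)
}

#' Hubs per 1,000 binding events
#'
#' Normalizes the hub count of one cell by its total number of binding
#' events, scaled to events per thousand.
#'
#' @param hubs A `hub_set` (or an integer hub count).
#' @param n_events_total Total binding events in the cell (>= 1).
#' @return `1000 * n_hubs / n_events_total`.
#' @export
hubs_per_1000 <- function(hubs, n_events_total) {
  n_hubs <- if (inherits(hubs, "hub_set")) nrow(hubs$hubs) else as.numeric(hubs)
  if (!is_count(n_events_total) || n_events_total < 1)
    stopf("n_events_total must be a positive count")
  1000 * n_hubs / n_events_total
}

#' Revisit latencies within hubs
#'
#' Time intervals between successive binding events in a hub: events are
#' ordered by start time and each latency is the next event's start minus
#' the previous event's end. Overlapping events produce negative raw
#' intervals, which are clamped to zero and flagged.
#'
#' @param hubs A `hub_set` from [label_hubs()], or a single member data
#'   frame with `start_t` and `end_t`.
#' @return A data frame with `hub_id`, `latency_s`, `clamped`; hubs with
#'   fewer than two events contribute no rows.
#' @export
hub_latencies <- function(hubs) {
  one <- function(df, id) {
    if (nrow(df) < 2L)
      return(data.frame(hub_id = integer(0), latency_s = numeric(0),
                        clamped = logical(0)))
    df <- df[order(df$start_t), , drop = FALSE]
    raw <- df$start_t[-1] - df$end_t[-nrow(df)]
    data.frame(hub_id = id, latency_s = pmax(raw, 0), clamped = raw < 0)
  }
  if (inherits(hubs, "hub_set")) {
    out <- mapply(one, hubs$members, hubs$hubs$hub_id, SIMPLIFY = FALSE)
    out <- do.call(rbind, c(out, list(one(data.frame(start_t = numeric(0),
                                                     end_t = numeric(0)), 0L))))
    rownames(out) <- NULL
    out
  } else one(hubs, 1L)
}
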