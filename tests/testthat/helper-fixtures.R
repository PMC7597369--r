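# Shared fixtures: small simulation configs and hand-built track tables.

# A small, fast nucleus: few events, no degradation unless overridden.
clean_config <- function(..., seed = 1L) {
  defaults <- list(n_events_per_channel = 200L, hub_count = 0L,
                   coloc_fraction = 0,
                   label_fraction = c(pold = 1, pcna = 1),
                   bleach_tau_s = c(pold = Inf, pcna = Inf),
                   loc_noise_sigma_nm = 0, blink_gap_prob = 0, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Build an smt_tracks object from explicit per-track specs:
# a data.frame with columns channel, t0 (first frame time), n (frames),
# x, y (nm); frame_interval dt. Channel grid offsets are respected.
make_tracks <- function(spec, dt = 1.34, n_frames = 1000L) {
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    ch <- spec$channel[i]
    off <- if (ch == "pold") dt / 2 else 0
    k0 <- round((spec$t0[i] - off) / dt)
    frames <- seq.int(k0, k0 + spec$n[i] - 1L)
    data.frame(track_id = i, channel = ch, frame = frames,
               t_s = frames * dt + off, x_nm = spec$x[i], y_nm = spec$y[i],
               intensity = 1000)
  })
  tab <- do.call(rbind, rows)
  tracks_from_table(tab, dt, n_frames)
}

# Independent exponential-mixture sampler (inverse-CDF, written without
# rexp) used as a second-implementation oracle for the generator.
oracle_mixture <- function(n, w, tau) {
  u <- stats::runif(n)
  comp <- findInterval(u, cumsum(w), left.open = TRUE) + 1L
  -tau[comp] * log(stats::runif(n))
}

# Ray-casting point-in-polygon oracle (crossing number), independent of
# mgcv. Points on the boundary are resolved separately by the caller.
oracle_in_polygon <- function(poly, x, y) {
  n <- nrow(poly) - 1L
  out <- logical(length(x))
  for (p in seq_along(x)) {
    crossings <- 0L
    for (i in seq_len(n)) {
      x1 <- poly[i, 1]; y1 <- poly[i, 2]
      x2 <- poly[i + 1, 1]; y2 <- poly[i + 1, 2]
      if ((y1 > y[p]) != (y2 > y[p])) {
        xint <- x1 + (y[p] - y1) / (y2 - y1) * (x2 - x1)
        if (x[p] < xint) crossings <- crossings + 1L
      }
    }
    out[p] <- crossings %% 2L == 1L
  }
  out
}

# Brute-force colocalization oracle: O(n^2) scan implementing the
# definition directly (closed-interval time overlap, window-averaged
# positions, strict radius, polymerase-centric nearest pairing with
# longer-overlap tie-break).
oracle_coloc <- function(pold, pcna, radius = 47, min_pold = 1.34,
                         dt = 1.34) {
  p <- as.data.frame(pold); q <- as.data.frame(pcna)
  pl <- track_locs(pold); ql <- track_locs(pcna)
  p <- p[p$duration_s > min_pold, , drop = FALSE]
  res <- list()
  for (i in seq_len(nrow(p))) {
    best <- NULL
    for (j in seq_len(nrow(q))) {
      if (p$start_t[i] > q$end_t[j] || q$start_t[j] > p$end_t[i]) next
      t0 <- max(p$start_t[i], q$start_t[j])
      t1 <- min(p$end_t[i], q$end_t[j])
      li <- pl[pl$track_id == p$track_id[i], ]
      lj <- ql[ql$track_id == q$track_id[j], ]
      si <- li$t_s >= t0 & li$t_s <= t1
      sj <- lj$t_s >= t0 & lj$t_s <= t1
      if (!any(si)) si <- li$t_s >= t0 - dt / 2 & li$t_s <= t1 + dt / 2
      if (!any(sj)) sj <- lj$t_s >= t0 - dt / 2 & lj$t_s <= t1 + dt / 2
      if (!any(si) || !any(sj)) next
      sep <- sqrt((mean(li$x_nm[si]) - mean(lj$x_nm[sj]))^2 +
                    (mean(li$y_nm[si]) - mean(lj$y_nm[sj]))^2)
      if (sep >= radius) next
      cand <- list(j = j, sep = sep, overlap = t1 - t0)
      if (is.null(best) || cand$sep < best$sep - 1e-12 ||
          (abs(cand$sep - best$sep) <= 1e-12 &&
             cand$overlap > best$overlap))
        best <- cand
    }
    if (!is.null(best))
      res[[length(res) + 1L]] <- data.frame(
        pold_track = p$track_id[i], pcna_track = q$track_id[best$j],
        sep_nm = best$sep)
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(pold_track = integer(0), pcna_track = integer(0),
               sep_nm = numeric(0))
}

# naive per-pixel octagon window count, restricted to a pixel set
naive_window_counts <- function(events, pixels, kernel) {
  off <- attr(kernel, "offsets")
  vapply(seq_len(nrow(pixels)), function(p) {
    dx <- events$ix - pixels$ix[p]
    dy <- events$iy - pixels$iy[p]
    sum(vapply(seq_along(dx), function(i)
      any(off[, "dx"] == dx[i] & off[, "dy"] == dy[i]), TRUE))
  }, 0L)
}
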