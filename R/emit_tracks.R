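#' Emit observed track tables from ground truth
#'
#' Applies the detection-degrading effects to ground-truth events and
#' discretizes them onto the alternating-channel frame grid, producing the
#' per-localization track table that the analysis stages consume. Each
#' event is independently retained with its channel's labeling probability;
#' a per-molecule photobleach time is drawn from the channel's exponential
#' bleach distribution and truncates the observed interval; positions are
#' perturbed per frame by isotropic Gaussian localization noise; interior
#' frames are dropped with the blinking probability (runs of consecutive
#' misses capped at 3 frames so gap closing at 5 s can always bridge them).
#'
#' The clamp channel is sampled at `t = k * dt`, the polymerase channel at
#' `t = k * dt + dt/2` (k = 0-based frame, dt = frame interval), matching
#' an alternating filter-wheel acquisition.
#'
#' @param truth An `smt_truth` data frame from [generate_truth()].
#' @param config The same [sim_config()] used to generate `truth`.
#' @return A data frame of class `smt_loc_table` with columns `track_id`
#'   (the ground-truth `event_id`), `channel`, `frame` (0-based, per
#'   channel), `t_s`, `x_nm`, `y_nm`, `intensity`. Attributes: `config`,
#'   and `bleach_s`, the per-event drawn bleach times (named by event id).
#' @examples
#' cfg <- sim_config(n_events_per_channel = 50, seed = 3)
#' tab <- emit_tracks(generate_truth(cfg), cfg)
#' head(tab)
#' @export
emit_tracks <- function(truth, config) {
  if (!inherits(truth, "smt_truth")) stopf("truth must come from generate_truth")
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  local_seed(child_seed(config$seed, "emit"), {
    cfg <- config
    dt <- cfg$frame_interval_s
    n <- nrow(truth)
    keep <- stats::runif(n) < cfg$label_fraction[truth$channel]
    bleach <- numeric(n)
    for (ch in CHANNELS) {
      idx <- truth$channel == ch
      tau_b <- cfg$bleach_tau_s[[ch]]
      bleach[idx] <- if (is.finite(tau_b))
        stats::rexp(sum(idx), 1 / tau_b) else Inf
    }
    obs_dur <- pmin(truth$duration_s, bleach)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      if (!keep[i]) next
      ch <- truth$channel[i]
      off <- channel_offset(ch, dt)
      t0 <- truth$start_s[i]
      t1 <- t0 + obs_dur[i]
      k0 <- ceiling((t0 - off) / dt)
      k1 <- floor((t1 - off) / dt)
      k0 <- max(k0, 0L)
      k1 <- min(k1, cfg$movie_length_frames - 1L)
      if (k1 < k0) next
      frames <- seq.int(k0, k1)
      nf <- length(frames)
      present <- rep(TRUE, nf)
      if (cfg$blink_gap_prob > 0 && nf > 2L) {
        drop <- stats::runif(nf - 2L) < cfg$blink_gap_prob
        run <- 0L
        for (j in seq_len(nf - 2L)) {
          if (drop[j]) {
            run <- run + 1L
            if (run > 3L) { drop[j] <- FALSE; run <- 0L }
          } else run <- 0L
        }
        present[1L + which(drop)] <- FALSE
      }
      frames <- frames[present]
      nf <- length(frames)
      noise <- if (cfg$loc_noise_sigma_nm > 0)
        matrix(stats::rnorm(2L * nf, 0, cfg$loc_noise_sigma_nm), ncol = 2L)
      else matrix(0, nf, 2L)
      rows[[i]] <- data.frame(
        track_id = truth$event_id[i], channel = ch, frame = frames,
        t_s = frames * dt + off,
        x_nm = truth$x_nm[i] + noise[, 1L],
        y_nm = truth$y_nm[i] + noise[, 2L],
        intensity = 1000 * exp(stats::rnorm(nf, 0, 0.2)),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, c(rows[!vapply(rows, is.null, TRUE)],
                            list(empty_loc_table())))
    out <- out[order(out$channel, out$track_id, out$frame), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "config") <- cfg
    attr(out, "pixel_size_nm") <- cfg$pixel_size_nm
    bl <- bleach
    names(bl) <- truth$event_id
    attr(out, "bleach_s") <- bl
    class(out) <- c("smt_loc_table", "data.frame")
    out
  })
}

empty_loc_table <- function() {
  data.frame(track_id = integer(0), channel = character(0),
             frame = integer(0), t_s = numeric(0), x_nm = numeric(0),
             y_nm = numeric(0), intensity = numeric(0),
             stringsAsFactors = FALSE)
}

#' Read or write a track table
#'
#' Track tables are plain comma-separated text with the fixed header
#' `track_id,channel,frame,t_s,x_nm,y_nm,intensity`, the interchange
#' format between the simulator, the tracker, and the analysis stages.
#'
#' @param x A track-table data frame.
#' @param path File path.
#' @param pixel_size_nm Pixel size recorded alongside the table (used to
#'   detect mismatched coordinate frames when two tables are combined).
#' @return `read_tracks` returns an `smt_loc_table` data frame.
#' @export
write_tracks <- function(x, path) {
  cols <- c("track_id", "channel", "frame", "t_s", "x_nm", "y_nm", "intensity")
  if (!all(cols %in% names(x))) stopf("track table lacks required columns")
  out <- as.data.frame(x)[, cols]
  # serialize doubles at full precision so tables round-trip exactly
  for (cc in c("t_s", "x_nm", "y_nm", "intensity"))
    out[[cc]] <- formatC(out[[cc]], digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path, pixel_size_nm = 84) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("track_id", "channel", "frame", "t_s", "x_nm", "y_nm", "intensity")
  if (!all(cols %in% names(out))) stopf("%s is not a track table", path)
  check_channel(unique(out$channel))
  attr(out, "pixel_size_nm") <- pixel_size_nm
  class(out) <- c("smt_loc_table", "data.frame")
  out
}
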