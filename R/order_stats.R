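#' Randomize track positions within the nucleus
#'
#' Positional-randomization null for colocalization: every track's mean
#' position is replaced by an independent uniform draw over the nuclear
#' ROI (channel-independently; no pair structure is preserved), and its
#' localizations are rigidly translated along. Durations, frames, and
#' channel identities are untouched, so re-running colocalization
#' detection on the result measures the chance-overlap frequency.
#'
#' @param tracks An `smt_tracks` object whose tracks lie inside `roi`.
#' @param roi A `nucleus_roi`.
#' @param seed Integer seed; different seeds give independent draws.
#' @return An `smt_tracks` object with randomized positions.
#' @export
randomize_positions <- function(tracks, roi, seed = 1L) {
  stopifnot(inherits(tracks, "smt_tracks"), inherits(roi, "nucleus_roi"))
  n <- nrow(tracks)
  local_seed(child_seed(seed, "randomize"), {
    pos <- sample_in_roi(roi, n)
    out <- as.data.frame(tracks)
    shift_x <- pos[, 1] - out$mean_x
    shift_y <- pos[, 2] - out$mean_y
    out$mean_x <- pos[, 1]
    out$mean_y <- pos[, 2]
    locs <- track_locs(tracks)
    idx <- match(paste(locs$channel, locs$track_id),
                 paste(out$channel, out$track_id))
    locs$x_nm <- locs$x_nm + shift_x[idx]
    locs$y_nm <- locs$y_nm + shift_y[idx]
    new_tracks(out, locs, attr(tracks, "frame_interval_s"))
  })
}

#' Bootstrap the arrival/departure order fractions
#'
#' Resamples colocalization events with replacement and reports, for each
#' arrival and departure class, the observed count, fraction, and the
#' bootstrap standard deviation of the fraction.
#'
#' @param events A classified `coloc_events` data frame.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed (resampling is deterministic given it).
#' @return An object of class `order_summary`: list with `n_events`,
#'   `n_boot`, and data frames `arrival` and `departure`
#'   (`class`, `count`, `fraction`, `sd`).
#' @export
bootstrap_order_fractions <- function(events, n_boot = 1000L, seed = 1L) {
  if (nrow(events) < 1L) stopf("need at least one event")
  arr_classes <- c("pcna_first", "pold_first", "simultaneous")
  dep_classes <- c("pold_first", "pcna_first", "simultaneous")
  n <- nrow(events)
  frac <- function(x, classes) {
    tab <- table(factor(x, levels = classes))
    as.numeric(tab) / length(x)
  }
  local_seed(child_seed(seed, "order-boot"), {
    boot_a <- matrix(0, n_boot, length(arr_classes))
    boot_d <- matrix(0, n_boot, length(dep_classes))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      boot_a[b, ] <- frac(events$arrival[idx], arr_classes)
      boot_d[b, ] <- frac(events$departure[idx], dep_classes)
    }
    sd0 <- function(m) if (n_boot > 1L) apply(m, 2, stats::sd) else
      rep(0, ncol(m))
    summ <- function(x, classes, sds) data.frame(
      class = classes,
      count = as.integer(table(factor(x, levels = classes))),
      fraction = frac(x, classes), sd = sds, stringsAsFactors = FALSE)
    structure(list(
      n_events = n, n_boot = n_boot,
      arrival = summ(events$arrival, arr_classes, sd0(boot_a)),
      departure = summ(events$departure, dep_classes, sd0(boot_d))),
      class = "order_summary")
  })
}

#' @export
print.order_summary <- function(x, ...) {
  cat(sprintf("Order of binding over %d colocalization events (%d bootstrap)\n",
              x$n_events, x$n_boot))
  cat("  arrivals:\n"); print(x$arrival, row.names = FALSE)
  cat("  departures:\n"); print(x$departure, row.names = FALSE)
  invisible(x)
}

#' Assembly/disassembly pathway quadrants
#'
#' Cross-tabulates non-simultaneous arrival and departure classes into the
#' four assembly/disassembly pathway quadrants. For each quadrant it
#' reports the fraction of all colocalizations and the median pre-, joint-,
#' and post-colocalization intervals with bootstrap confidence intervals.
#' Events with a simultaneous arrival or departure are tallied separately
#' in the `simultaneous` component.
#'
#' @param events A classified `coloc_events` data frame.
#' @param n_boot Bootstrap replicates for the median CIs.
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return An object of class `quadrant_summary`: list with `quadrants`
#'   (data frame: `arrival`, `departure`, `n`, `fraction`, `median_pre_s`,
#'   `pre_lo`, `pre_hi`, `median_coloc_s`, `coloc_lo`, `coloc_hi`,
#'   `median_post_s`, `post_lo`, `post_hi`), `simultaneous` (counts of
#'   events excluded per margin), and `n_events`.
#' @export
quadrant_analysis <- function(events, n_boot = 1000L, conf = 0.95,
                              seed = 1L) {
  n <- nrow(events)
  grid <- expand.grid(arrival = c("pcna_first", "pold_first"),
                      departure = c("pold_first", "pcna_first"),
                      stringsAsFactors = FALSE)
  alpha <- (1 - conf) / 2
  rows <- vector("list", nrow(grid))
  local_seed(child_seed(seed, "quadrants"), {
    for (g in seq_len(nrow(grid))) {
      sel <- events$arrival == grid$arrival[g] &
        events$departure == grid$departure[g]
      ev <- events[sel, , drop = FALSE]
      med_ci <- function(v) {
        if (nrow(ev) == 0L) return(c(NA_real_, NA_real_, NA_real_))
        boots <- vapply(seq_len(n_boot), function(b)
          stats::median(v[sample.int(length(v), replace = TRUE)]), 0)
        c(stats::median(v), stats::quantile(boots, alpha, names = FALSE),
          stats::quantile(boots, 1 - alpha, names = FALSE))
      }
      pre <- med_ci(ev$pre_s); col <- med_ci(ev$coloc_s)
      post <- med_ci(ev$post_s)
      rows[[g]] <- data.frame(
        arrival = grid$arrival[g], departure = grid$departure[g],
        n = nrow(ev), fraction = if (n) nrow(ev) / n else NA_real_,
        median_pre_s = pre[1], pre_lo = pre[2], pre_hi = pre[3],
        median_coloc_s = col[1], coloc_lo = col[2], coloc_hi = col[3],
        median_post_s = post[1], post_lo = post[2], post_hi = post[3],
        stringsAsFactors = FALSE)
    }
  })
  structure(list(
    quadrants = do.call(rbind, rows),
    simultaneous = c(arrival = sum(events$arrival == "simultaneous"),
                     departure = sum(events$departure == "simultaneous")),
    n_events = n), class = "quadrant_summary")
}

#' @export
print.quadrant_summary <- function(x, ...) {
  cat(sprintf("Pathway quadrants over %d events (%d with simultaneous arrival, %d departure)\n",
              x$n_events, x$simultaneous["arrival"],
              x$simultaneous["departure"]))
  print(x$quadrants[, c("arrival", "departure", "n", "fraction",
                        "median_pre_s", "median_coloc_s", "median_post_s")],
        row.names = FALSE)
  invisible(x)
}
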