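#' Generate ground-truth binding events for a synthetic nucleus
#'
#' Draws one nucleus worth of true chromatin-binding events in continuous
#' time (seconds) and space (nm), before any detection effect is applied.
#' The polymerase channel receives `hub_count` planted hubs -- chains of
#' revisiting events whose inter-visit latencies follow the configured
#' three-component exponential mixture -- plus spatially uniform background
#' events. A configurable fraction of polymerase events carries a
#' colocalized clamp partner whose arrival/departure order relative to the
#' polymerase event is drawn from the configured order distributions; the
#' remaining clamp-channel events are independent background. All residence
#' times come from the configured exponential mixture.
#'
#' Truth is resolution-free: times are not yet snapped to the frame grid
#' and events may extend beyond the movie end (emission clips them).
#'
#' @param config A [sim_config()] object.
#' @return A data frame of class `smt_truth`, one row per event, with
#'   columns `event_id`, `channel`, `start_s`, `duration_s`, `x_nm`,
#'   `y_nm`, `population` (residence mixture component, `NA` for planted
#'   partners), `hub_id`, `partner_id`, `arrival_class`, `departure_class`.
#'   The configuration is attached as attribute `config`.
#' @examples
#' truth <- generate_truth(sim_config(n_events_per_channel = 100, seed = 2))
#' table(truth$channel)
#' @export
generate_truth <- function(config) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  validate_sim_config(config)
  local_seed(child_seed(config$seed, "truth"), {
    cfg <- config
    center <- c(cfg$field_size_px[1], cfg$field_size_px[2]) *
      cfg$pixel_size_nm / 2
    movie_s <- cfg$movie_length_frames * cfg$frame_interval_s

    ## --- polymerase channel: hubs then background ---
    hub_rows <- list()
    if (cfg$hub_count > 0L) {
      inner <- cfg$nucleus_semiaxes_nm - cfg$hub_radius_nm
      centers <- runif_ellipse(cfg$hub_count, inner, center)
      for (h in seq_len(cfg$hub_count)) {
        n_h <- 3L + stats::rpois(1L, max(cfg$hub_events_mean - 3, 0))
        ang <- stats::runif(n_h, 0, 2 * pi)
        rad <- cfg$hub_radius_nm * sqrt(stats::runif(n_h))
        dur <- if (cfg$hub_long_lived) {
          long <- which.max(cfg$residence_tau_s)
          structure(stats::rexp(n_h, 1 / cfg$residence_tau_s[long]),
                    component = rep(long, n_h))
        } else rexp_mixture(n_h, cfg$residence_weights, cfg$residence_tau_s)
        lat <- rexp_mixture(n_h - 1L, cfg$latency_weights, cfg$latency_tau_s)
        start <- numeric(n_h)
        start[1] <- stats::runif(1, 0, movie_s)
        if (n_h > 1L)
          start[-1] <- start[1] + cumsum(dur[-n_h] + lat)
        hub_rows[[h]] <- data.frame(
          channel = "pold", start_s = start, duration_s = as.numeric(dur),
          x_nm = centers[h, 1] + rad * cos(ang),
          y_nm = centers[h, 2] + rad * sin(ang),
          population = attr(dur, "component"), hub_id = h,
          stringsAsFactors = FALSE)
      }
    }
    hubs <- if (length(hub_rows)) do.call(rbind, hub_rows) else NULL
    n_hub_events <- if (is.null(hubs)) 0L else nrow(hubs)
    n_bg <- max(cfg$n_events_per_channel - n_hub_events, 0L)
    bg_pos <- runif_ellipse(n_bg, cfg$nucleus_semiaxes_nm, center)
    bg_dur <- rexp_mixture(n_bg, cfg$residence_weights, cfg$residence_tau_s)
    bg <- data.frame(
      channel = rep("pold", n_bg), start_s = stats::runif(n_bg, 0, movie_s),
      duration_s = as.numeric(bg_dur), x_nm = bg_pos[, "x"],
      y_nm = bg_pos[, "y"],
      population = attr(bg_dur, "component"),
      hub_id = rep(NA_integer_, n_bg),
      stringsAsFactors = FALSE)
    pold <- rbind(hubs, bg)
    pold$partner_id <- NA_integer_
    pold$arrival_class <- NA_character_
    pold$departure_class <- NA_character_

    ## --- planted colocalized clamp partners ---
    eligible <- which(pold$duration_s >= cfg$frame_interval_s)
    is_coloc <- stats::runif(nrow(pold)) < cfg$coloc_fraction
    coloc_idx <- intersect(which(is_coloc), eligible)
    partners <- if (length(coloc_idx))
      plant_partners(pold[coloc_idx, , drop = FALSE], cfg) else NULL

    ## --- clamp background ---
    n_pcna_bg <- max(cfg$n_events_per_channel -
                       if (is.null(partners)) 0L else nrow(partners$events),
                     0L)
    pb_pos <- runif_ellipse(n_pcna_bg, cfg$nucleus_semiaxes_nm, center)
    pb_dur <- rexp_mixture(n_pcna_bg, cfg$residence_weights,
                           cfg$residence_tau_s)
    pcna_bg <- data.frame(
      channel = rep("pcna", n_pcna_bg),
      start_s = stats::runif(n_pcna_bg, 0, movie_s),
      duration_s = as.numeric(pb_dur), x_nm = pb_pos[, "x"],
      y_nm = pb_pos[, "y"],
      population = attr(pb_dur, "component"),
      hub_id = rep(NA_integer_, n_pcna_bg),
      partner_id = rep(NA_integer_, n_pcna_bg),
      arrival_class = rep(NA_character_, n_pcna_bg),
      departure_class = rep(NA_character_, n_pcna_bg),
      stringsAsFactors = FALSE)

    truth <- rbind(pold, if (!is.null(partners)) partners$events, pcna_bg)
    truth$event_id <- seq_len(nrow(truth))
    if (!is.null(partners)) {
      # symmetric partner links; coloc_idx rows are the matching pold events
      pold_ids <- truth$event_id[coloc_idx]
      pcna_ids <- truth$event_id[truth$channel == "pcna" &
                                   !is.na(truth$arrival_class)]
      truth$partner_id[match(pold_ids, truth$event_id)] <- pcna_ids
      truth$partner_id[match(pcna_ids, truth$event_id)] <- pold_ids
      truth$arrival_class[match(pold_ids, truth$event_id)] <-
        partners$events$arrival_class
      truth$departure_class[match(pold_ids, truth$event_id)] <-
        partners$events$departure_class
    }
    truth <- truth[, c("event_id", "channel", "start_s", "duration_s",
                       "x_nm", "y_nm", "population", "hub_id",
                       "partner_id", "arrival_class", "departure_class")]
    rownames(truth) <- NULL
    attr(truth, "config") <- cfg
    class(truth) <- c("smt_truth", "data.frame")
    truth
  })
}

# Given the polymerase events that receive a partner, construct the clamp
# partner events implementing the planted arrival/departure order classes.
# Non-simultaneous gaps are >= 2 frame intervals so the class survives
# discretization; classes that cannot be realized for a short polymerase
# event (the partner interval would not overlap) are re-drawn among the
# feasible classes with renormalized probabilities.
plant_partners <- function(pold_events, cfg) {
  n <- nrow(pold_events)
  dt <- cfg$frame_interval_s
  gap_min <- 2 * dt
  draw_gap <- function() gap_min + stats::rexp(1, 1 / cfg$order_interval_mean_s)
  arr <- character(n); dep <- character(n)
  p_start <- numeric(n); p_end <- numeric(n)
  for (i in seq_len(n)) {
    s <- pold_events$start_s[i]
    e <- s + pold_events$duration_s[i]
    d <- e - s
    arr_ok <- c(pcna_first = TRUE, simultaneous = TRUE,
                pold_first = d > gap_min + dt)
    a <- sample_class(cfg$arrival_probs, arr_ok)
    ps <- switch(a,
                 pcna_first = s - draw_gap(),
                 simultaneous = s,
                 pold_first = s + min(draw_gap(), d - dt))
    # departure feasibility given the partner must end after coloc starts
    coloc_start <- max(s, ps)
    dep_ok <- c(pold_first = TRUE, simultaneous = TRUE,
                pcna_first = (e - coloc_start) > gap_min + dt)
    b <- sample_class(cfg$departure_probs, dep_ok)
    pe <- switch(b,
                 pold_first = e + draw_gap(),
                 simultaneous = e,
                 pcna_first = e - min(draw_gap(), e - coloc_start - dt))
    arr[i] <- a; dep[i] <- b; p_start[i] <- ps; p_end[i] <- pe
  }
  off <- matrix(stats::rnorm(2 * n, 0, cfg$coloc_offset_scale_nm), ncol = 2)
  events <- data.frame(
    channel = rep("pcna", n), start_s = p_start,
    duration_s = p_end - p_start,
    x_nm = pold_events$x_nm + off[, 1], y_nm = pold_events$y_nm + off[, 2],
    population = NA_integer_, hub_id = NA_integer_,
    partner_id = NA_integer_, arrival_class = arr, departure_class = dep,
    stringsAsFactors = FALSE)
  list(events = events)
}

sample_class <- function(probs, feasible) {
  p <- probs[names(feasible)[feasible]]
  if (sum(p) <= 0) p <- rep(1, length(p))
  names(p)[sample.int(length(p), 1L, prob = p)]
}

#' @export
print.smt_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d events (%d pold, %d pcna), %d paired\n",
              nrow(x), sum(x$channel == "pold"), sum(x$channel == "pcna"),
              sum(!is.na(x$partner_id)) %/% 2L))
  NextMethod()
}
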