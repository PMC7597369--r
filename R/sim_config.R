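#' Simulation configuration for synthetic two-color SMT data
#'
#' Bundles every generative assumption of the synthetic-data module: the
#' nuclear geometry, acquisition timing, the two-population exponential
#' residence-time mixture, the colocalized-pair structure (fraction,
#' arrival/departure order distribution, spatial offset), binding hubs with
#' a three-component revisit-latency mixture, and the detection-degrading
#' effects (sparse labeling, photobleaching, localization noise, blinking).
#'
#' Defaults describe a single S-phase nucleus imaged by alternating-channel
#' HILO microscopy: 512 x 512 pixels at 84 nm/px, 1.34 s per channel frame
#' (a 500 ms exposure plus filter-wheel dead time, interleaved between the
#' two colors), an approximately 22-minute movie. Residence times default
#' to a 96%/4% mixture of 1.0 s and 12.4 s components; photobleaching
#' defaults to the measured dye time constants (99.3 s for the SiR-labeled
#' polymerase channel, 166.8 s for the JF549-labeled clamp channel).
#'
#' @param nucleus_semiaxes_nm Semi-axes (nm) of the elliptical nuclear mask.
#' @param field_size_px Field of view in pixels, `c(nx, ny)`.
#' @param pixel_size_nm Camera pixel size (nm).
#' @param frame_interval_s Per-channel frame interval (s). The two channels
#'   are interleaved: the clamp channel is exposed at `k * dt`, the
#'   polymerase channel at `k * dt + dt/2`.
#' @param movie_length_frames Number of frames per channel.
#' @param n_events_per_channel Ground-truth binding events per channel.
#' @param residence_weights,residence_tau_s Weights (sum 1) and time
#'   constants (s) of the exponential residence-time mixture.
#' @param coloc_fraction Fraction of polymerase events that have a planted
#'   colocalized clamp partner.
#' @param arrival_probs Named probabilities over arrival order classes
#'   `c(pcna_first, pold_first, simultaneous)`.
#' @param departure_probs Named probabilities over departure order classes
#'   `c(pold_first, pcna_first, simultaneous)`.
#' @param coloc_offset_scale_nm Isotropic Gaussian scale (nm, per axis) of
#'   the true spatial offset between partners.
#' @param order_interval_mean_s Mean (s) of the exponential part of planted
#'   partner-alone intervals. Non-simultaneous gaps are drawn as
#'   `2 * frame_interval_s + Exp(order_interval_mean_s)` so that
#'   discretization onto the frame grid cannot flip a planted class.
#' @param hub_count Number of planted binding hubs (polymerase channel).
#' @param hub_radius_nm Radius (nm) within which hub member events sit.
#' @param hub_events_mean Mean number of events per hub (minimum 3).
#' @param hub_long_lived If `TRUE` (default), hub member events draw their
#'   residence times from the stable (longest-tau) mixture component:
#'   repeated visits to a replication site are productive binding events,
#'   and the hub analysis considers only events longer than 1.7 s.
#' @param latency_weights,latency_tau_s Weights and time constants (s) of
#'   the three-component hub revisit-latency mixture.
#' @param label_fraction Named per-channel probability that a true event is
#'   fluorescently labeled (sparse labeling), in (0, 1].
#' @param bleach_tau_s Named per-channel photobleaching time constants (s);
#'   `Inf` disables bleaching.
#' @param loc_noise_sigma_nm Per-frame isotropic localization error (nm).
#' @param blink_gap_prob Probability that an interior frame of a track is
#'   missed (blinking); runs of misses are capped at 3 frames.
#' @param psf_sigma_px PSF Gaussian width (px) used when rendering movies.
#' @param seed Integer master seed; all generator randomness derives from it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_events_per_channel = 200, seed = 7)
#' cfg$residence_tau_s
#' @export
sim_config <- function(nucleus_semiaxes_nm = c(8000, 6000),
                       field_size_px = c(512L, 512L),
                       pixel_size_nm = 84,
                       frame_interval_s = 1.34,
                       movie_length_frames = 985L,
                       n_events_per_channel = 2000L,
                       residence_weights = c(0.96, 0.04),
                       residence_tau_s = c(1.0, 12.4),
                       coloc_fraction = 0.021,
                       arrival_probs = c(pcna_first = 0.79,
                                         pold_first = 0.10,
                                         simultaneous = 0.11),
                       departure_probs = c(pold_first = 0.84,
                                           pcna_first = 0.09,
                                           simultaneous = 0.07),
                       coloc_offset_scale_nm = 15,
                       order_interval_mean_s = 8,
                       hub_count = 30L,
                       hub_radius_nm = 84,
                       hub_events_mean = 5,
                       hub_long_lived = TRUE,
                       latency_weights = c(0.37, 0.43, 0.20),
                       latency_tau_s = c(8, 25, 200),
                       label_fraction = c(pold = 1, pcna = 1),
                       bleach_tau_s = c(pold = 99.3, pcna = 166.8),
                       loc_noise_sigma_nm = 25,
                       blink_gap_prob = 0.1,
                       psf_sigma_px = 1.5,
                       seed = 1L) {
  cfg <- list(
    nucleus_semiaxes_nm = as.numeric(nucleus_semiaxes_nm),
    field_size_px = as.integer(field_size_px),
    pixel_size_nm = as.numeric(pixel_size_nm),
    frame_interval_s = as.numeric(frame_interval_s),
    movie_length_frames = as.integer(movie_length_frames),
    n_events_per_channel = as.integer(n_events_per_channel),
    residence_weights = as.numeric(residence_weights),
    residence_tau_s = as.numeric(residence_tau_s),
    coloc_fraction = as.numeric(coloc_fraction),
    arrival_probs = arrival_probs,
    departure_probs = departure_probs,
    coloc_offset_scale_nm = as.numeric(coloc_offset_scale_nm),
    order_interval_mean_s = as.numeric(order_interval_mean_s),
    hub_count = as.integer(hub_count),
    hub_radius_nm = as.numeric(hub_radius_nm),
    hub_events_mean = as.numeric(hub_events_mean),
    hub_long_lived = isTRUE(hub_long_lived),
    latency_weights = as.numeric(latency_weights),
    latency_tau_s = as.numeric(latency_tau_s),
    label_fraction = label_fraction,
    bleach_tau_s = bleach_tau_s,
    loc_noise_sigma_nm = as.numeric(loc_noise_sigma_nm),
    blink_gap_prob = as.numeric(blink_gap_prob),
    psf_sigma_px = as.numeric(psf_sigma_px),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_mix <- function(w, tau, what) {
    if (length(w) != length(tau))
      stopf("%s: weights and time constants differ in length", what)
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
      stopf("%s: mixture weights must be nonnegative and sum to 1", what)
    if (any(tau <= 0))
      stopf("%s: all time constants must be > 0", what)
  }
  chk_mix(cfg$residence_weights, cfg$residence_tau_s, "residence mixture")
  chk_mix(cfg$latency_weights, cfg$latency_tau_s, "latency mixture")
  chk_probs <- function(p, classes, what) {
    if (!all(classes %in% names(p)))
      stopf("%s must be named with classes: %s", what,
            paste(classes, collapse = ", "))
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stopf("%s must be nonnegative and sum to 1", what)
  }
  chk_probs(cfg$arrival_probs, c("pcna_first", "pold_first", "simultaneous"),
            "arrival_probs")
  chk_probs(cfg$departure_probs, c("pold_first", "pcna_first", "simultaneous"),
            "departure_probs")
  if (length(cfg$nucleus_semiaxes_nm) != 2L || any(cfg$nucleus_semiaxes_nm <= 0))
    stopf("nucleus_semiaxes_nm must be two positive lengths")
  if (cfg$hub_radius_nm >= min(cfg$nucleus_semiaxes_nm))
    stopf("hub_radius_nm must be smaller than the smallest nuclear semi-axis")
  if (!all(CHANNELS %in% names(cfg$label_fraction)))
    stopf("label_fraction must be named c(pold = , pcna = )")
  if (any(cfg$label_fraction <= 0) || any(cfg$label_fraction > 1))
    stopf("label fractions must lie in (0, 1]")
  if (!all(CHANNELS %in% names(cfg$bleach_tau_s)))
    stopf("bleach_tau_s must be named c(pold = , pcna = )")
  if (any(cfg$bleach_tau_s <= 0))
    stopf("bleach_tau_s must be > 0 (use Inf to disable)")
  if (cfg$frame_interval_s <= 0) stopf("frame_interval_s must be > 0")
  if (cfg$movie_length_frames < 2L) stopf("movie_length_frames must be >= 2")
  if (cfg$coloc_fraction < 0 || cfg$coloc_fraction > 1)
    stopf("coloc_fraction must lie in [0, 1]")
  if (cfg$blink_gap_prob < 0 || cfg$blink_gap_prob >= 1)
    stopf("blink_gap_prob must lie in [0, 1)")
  if (cfg$hub_events_mean < 3)
    stopf("hub_events_mean must be >= 3 (hubs require at least 3 events)")
  if (cfg$loc_noise_sigma_nm < 0) stopf("loc_noise_sigma_nm must be >= 0")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  dur <- x$movie_length_frames * x$frame_interval_s
  cat("Synthetic two-color SMT configuration\n")
  cat(sprintf("  field: %d x %d px at %.1f nm/px; nucleus %0.f x %0.f nm\n",
              x$field_size_px[1], x$field_size_px[2], x$pixel_size_nm,
              2 * x$nucleus_semiaxes_nm[1], 2 * x$nucleus_semiaxes_nm[2]))
  cat(sprintf("  %d frames/channel at %.2f s (%.0f s movie)\n",
              x$movie_length_frames, x$frame_interval_s, dur))
  cat(sprintf("  residence mixture: f = (%s), tau = (%s) s\n",
              paste(format(x$residence_weights), collapse = ", "),
              paste(format(x$residence_tau_s), collapse = ", ")))
  cat(sprintf("  %d events/channel, coloc fraction %.3f, %d hubs\n",
              x$n_events_per_channel, x$coloc_fraction, x$hub_count))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
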