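#' Pipeline run configuration
#'
#' Collects every analysis parameter with defaults fixed at the study
#' constants: 47 nm colocalization radius, 1.34 s minimum polymerase
#' duration and frame interval, 1.7 s short/long residence threshold,
#' 0.05 um^2/s linking diffusion gate, 5 s maximum gap, 168 nm octagon
#' window with >= 3 events on a 10x expanded map, 1,000 bootstrap
#' iterations.
#'
#' @param n_cells Number of nuclei to simulate/analyze.
#' @param seed Master seed; each cell and stage derives a child seed.
#' @param sim A [sim_config()] used as per-cell template in simulate/full
#'   modes (its own seed is replaced per cell).
#' @param radius_nm,min_pold_s,simultaneity_tol_s Colocalization settings.
#' @param stable_threshold_s Short/long residence split (s).
#' @param d_max_um2_s,max_gap_s Linking settings.
#' @param hub_diameter_nm,hub_min_events,expand_factor,hub_min_duration_s
#'   Hub detection settings.
#' @param n_boot Bootstrap iterations.
#' @param n_random_seeds Positional-randomization replicates for the
#'   chance-colocalization null (0 disables).
#' @param out_dir Output directory (`NULL`: nothing written).
#' @return A `run_config` list.
#' @export
run_config <- function(n_cells = 5L, seed = 1L, sim = sim_config(),
                       radius_nm = 47, min_pold_s = 1.34,
                       simultaneity_tol_s = NULL,
                       stable_threshold_s = 1.7,
                       d_max_um2_s = 0.05, max_gap_s = 5,
                       hub_diameter_nm = 168, hub_min_events = 3L,
                       expand_factor = 10L, hub_min_duration_s = 1.7,
                       n_boot = 1000L, n_random_seeds = 20L,
                       out_dir = NULL) {
  cfg <- list(n_cells = as.integer(n_cells), seed = as.integer(seed),
              sim = sim, radius_nm = radius_nm, min_pold_s = min_pold_s,
              simultaneity_tol_s = simultaneity_tol_s %||%
                sim$frame_interval_s,
              stable_threshold_s = stable_threshold_s,
              d_max_um2_s = d_max_um2_s, max_gap_s = max_gap_s,
              hub_diameter_nm = hub_diameter_nm,
              hub_min_events = as.integer(hub_min_events),
              expand_factor = as.integer(expand_factor),
              hub_min_duration_s = hub_min_duration_s,
              n_boot = as.integer(n_boot),
              n_random_seeds = as.integer(n_random_seeds),
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> track tables -> nuclear filtering ->
#' colocalization and order statistics -> residence-time fits -> hub
#' detection and latency fits, and assembles a machine-readable report.
#'
#' Modes: `"simulate"` generates per-cell ground truth and track tables
#' and stops; `"analyze"` runs the analysis on supplied per-cell track
#' tables; `"full"` does both. When `config$out_dir` is set, the resolved
#' configuration, per-cell track tables, event tables, and the JSON
#' report are written there.
#'
#' @param config A [run_config()].
#' @param mode One of `"full"`, `"simulate"`, `"analyze"`.
#' @param cells For `mode = "analyze"`: list of per-cell `smt_loc_table`
#'   data frames (or paths readable by [read_tracks()]).
#' @return A report list (class `smt_report`) with components `config`,
#'   `cells` (per-cell tables and inputs), `coloc`, `order`, `quadrants`,
#'   `residence`, `hubs`, `latency`, each mirroring one summary panel of
#'   the analysis.
#' @export
run_pipeline <- function(config = run_config(),
                         mode = c("full", "simulate", "analyze"),
                         cells = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "run_config"))
  sim <- config$sim
  report <- list(config = config, mode = mode)

  if (mode %in% c("full", "simulate")) {
    cells <- vector("list", config$n_cells)
    truths <- vector("list", config$n_cells)
    for (i in seq_len(config$n_cells)) {
      cell_cfg <- sim
      cell_cfg$seed <- child_seed(config$seed, paste0("cell", i))
      truth <- generate_truth(cell_cfg)
      cells[[i]] <- emit_tracks(truth, cell_cfg)
      truths[[i]] <- truth
    }
    report$truths <- truths
    if (mode == "simulate") {
      report$cells <- cells
      class(report) <- "smt_report"
      write_report(report, config$out_dir)
      return(invisible(report))
    }
  } else {
    if (is.null(cells)) stopf("mode 'analyze' needs per-cell track tables")
    cells <- lapply(cells, function(x)
      if (is.character(x)) read_tracks(x, sim$pixel_size_nm) else x)
  }
  report$cells <- cells

  dt <- sim$frame_interval_s
  roi <- ellipse_roi(sim$nucleus_semiaxes_nm,
                     center = sim$field_size_px * sim$pixel_size_nm / 2,
                     pixel_size_nm = sim$pixel_size_nm)
  per_cell <- vector("list", length(cells))
  all_events <- list()
  obs_freq <- numeric(0); null_freq <- numeric(0)
  hub_rates <- numeric(0); latencies <- list()
  res_rows <- list()
  for (i in seq_along(cells)) {
    trk <- tracks_from_table(cells[[i]], dt, sim$movie_length_frames)
    trk <- filter_nuclear_tracks(trk, roi)
    pold <- channel_tracks(trk, "pold")
    pcna <- channel_tracks(trk, "pcna")
    ev <- detect_colocalizations(pold, pcna, config$radius_nm,
                                 config$min_pold_s,
                                 simultaneity_tol_s =
                                   config$simultaneity_tol_s)
    n_qual <- attr(ev, "n_pold_qualifying")
    if (n_qual > 0) obs_freq <- c(obs_freq, colocalization_frequency(ev))
    all_events[[i]] <- ev
    if (config$n_random_seeds > 0L && nrow(pold) && nrow(pcna)) {
      for (s in seq_len(config$n_random_seeds)) {
        rp <- randomize_positions(pold, roi,
                                  child_seed(config$seed,
                                             paste0("rand", i, "_", s)))
        rq <- randomize_positions(pcna, roi,
                                  child_seed(config$seed,
                                             paste0("randq", i, "_", s)))
        re <- detect_colocalizations(rp, rq, config$radius_nm,
                                     config$min_pold_s)
        if (attr(re, "n_pold_qualifying") > 0)
          null_freq <- c(null_freq, colocalization_frequency(re))
      }
    }
    # per-cell residence fits (uncensored durations)
    cellfits <- list()
    for (ch in CHANNELS) {
      dur <- residence_times(trk, ch)
      fit <- tryCatch(fit_residence_times(dur, k_max = 2L,
                                          source = "residence_per_cell"),
                      error = function(e) NULL)
      if (!is.null(fit) && fit$k == 2L)
        res_rows[[length(res_rows) + 1L]] <- data.frame(
          cell = i, channel = ch, T1_s = fit$tau_s[1], T2_s = fit$tau_s[2],
          pct_T1 = 100 * fit$f[1], pct_T2 = 100 * fit$f[2], n = fit$n)
      cellfits[[ch]] <- fit
    }
    # hubs on the polymerase channel
    emap <- expand_map(pold, config$expand_factor, sim$pixel_size_nm,
                       sim$field_size_px, config$hub_min_duration_s)
    hubset <- label_hubs(scan_octagon(emap, config$hub_diameter_nm,
                                      config$hub_min_events))
    if (nrow(pold) > 0)
      hub_rates <- c(hub_rates, hubs_per_1000(hubset, nrow(pold)))
    lat <- hub_latencies(hubset)
    if (nrow(lat)) latencies[[length(latencies) + 1L]] <- lat$latency_s
    per_cell[[i]] <- list(n_tracks = table(trk$channel),
                          n_events = nrow(ev), hubs = hubset$hubs,
                          fits = cellfits)
  }
  events <- do.call(rbind, c(all_events, list(empty_coloc_events())))
  class(events) <- c("coloc_events", "data.frame")
  report$coloc <- list(
    n_events = nrow(events),
    frequency_pct = if (length(obs_freq)) mean(obs_freq) else NA_real_,
    per_cell_frequency_pct = obs_freq,
    randomized_frequency_pct = if (length(null_freq)) mean(null_freq)
    else NA_real_,
    median_coloc_s = if (nrow(events)) stats::median(events$coloc_s)
    else NA_real_)
  report$events <- events
  if (nrow(events)) {
    report$order <- bootstrap_order_fractions(events, config$n_boot,
                                              child_seed(config$seed, "boot"))
    report$quadrants <- quadrant_analysis(events, config$n_boot,
                                          seed = child_seed(config$seed,
                                                            "quad"))
  }
  report$residence <- if (length(res_rows)) do.call(rbind, res_rows)
  report$hubs <- list(per_1000 = hub_rates,
                      median_per_1000 = if (length(hub_rates))
                        stats::median(hub_rates) else NA_real_)
  pooled_lat <- unlist(latencies)
  if (length(pooled_lat) >= 30) {
    pooled_lat <- pooled_lat[pooled_lat > 0]
    lat_fit <- tryCatch(fit_residence_times(pooled_lat, k_max = 3L,
                                            source = "latency_pooled"),
                        error = function(e) NULL)
    report$latency <- list(n = length(pooled_lat), fit = lat_fit,
                           latencies = pooled_lat)
  }
  report$per_cell <- per_cell
  class(report) <- "smt_report"
  write_report(report, config$out_dir)
  invisible(report)
}

#' @export
print.smt_report <- function(x, ...) {
  cat(sprintf("SMT pipeline report (%s mode, %d cells)\n", x$mode,
              length(x$cells)))
  if (!is.null(x$coloc))
    cat(sprintf("  colocalization: %d events, %.3g%% of pold tracks (null %.3g%%)\n",
                x$coloc$n_events, x$coloc$frequency_pct,
                x$coloc$randomized_frequency_pct))
  if (!is.null(x$residence)) {
    agg <- stats::aggregate(cbind(T2_s, pct_T2) ~ channel, x$residence,
                            stats::median)
    for (r in seq_len(nrow(agg)))
      cat(sprintf("  %s: median T2 = %.3g s, %%T2 = %.3g\n",
                  agg$channel[r], agg$T2_s[r], agg$pct_T2[r]))
  }
  if (!is.null(x$hubs) && length(x$hubs$per_1000))
    cat(sprintf("  hubs: median %.3g per 1,000 events\n",
                x$hubs$median_per_1000))
  invisible(x)
}

# Serialize the machine-readable part of a report to out_dir (JSON + CSVs).
write_report <- function(report, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  cfg$sim <- unclass(cfg$sim)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  for (i in seq_along(report$cells))
    write_tracks(report$cells[[i]],
                 file.path(out_dir, sprintf("cell%02d_tracks.csv", i)))
  if (!is.null(report$events) && nrow(report$events))
    utils::write.csv(as.data.frame(report$events),
                     file.path(out_dir, "coloc_events.csv"),
                     row.names = FALSE)
  if (!is.null(report$residence))
    utils::write.csv(report$residence,
                     file.path(out_dir, "residence_per_cell.csv"),
                     row.names = FALSE)
  summary <- report_summary(report)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(file.path(out_dir, "report.json"))
}

#' Machine-readable summary of a pipeline report
#'
#' Flattens an `smt_report` into plain lists/vectors suitable for JSON.
#'
#' @param report An `smt_report`.
#' @return A named list.
#' @export
report_summary <- function(report) {
  out <- list(mode = report$mode, n_cells = length(report$cells))
  if (!is.null(report$coloc)) out$coloc <- report$coloc
  if (!is.null(report$order))
    out$order <- list(arrival = report$order$arrival,
                      departure = report$order$departure)
  if (!is.null(report$quadrants))
    out$quadrants <- list(table = report$quadrants$quadrants,
                          simultaneous =
                            as.list(report$quadrants$simultaneous))
  if (!is.null(report$residence)) out$residence <- report$residence
  if (!is.null(report$hubs)) out$hubs <- report$hubs
  if (!is.null(report$latency) && !is.null(report$latency$fit))
    out$latency <- list(n = report$latency$n,
                        k = report$latency$fit$k,
                        f = report$latency$fit$f,
                        tau_s = report$latency$fit$tau_s)
  out
}
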