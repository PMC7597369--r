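#' Render synthetic image stacks from a track table
#'
#' Draws every localization as a 2D Gaussian PSF on a 16-bit camera frame,
#' adds a constant background and (optionally) Poisson shot noise,
#' producing one stack per channel on the alternating-channel clock.
#' Localizations outside the field of view are clipped with a warning.
#'
#' @param locs A track-table data frame (from [emit_tracks()] or
#'   [read_tracks()]).
#' @param config A [sim_config()] (field size, pixel size, frame timing,
#'   PSF width).
#' @param background Constant background level (counts).
#' @param amplitude_scale Multiplies the table's `intensity` column to get
#'   the PSF peak amplitude in counts.
#' @param poisson_noise Add Poisson shot noise (seeded from the config).
#' @param channels Channels to render.
#' @return An object of class `smt_movie`: list with per-channel `stacks`
#'   (list of `nx x ny` matrices, counts), `frame_times` (list of numeric
#'   vectors, s), `pixel_size_nm`, and `config`.
#' @examples
#' cfg <- sim_config(field_size_px = c(64, 64), movie_length_frames = 3,
#'                   n_events_per_channel = 5, hub_count = 0, seed = 5)
#' mov <- render_movie(emit_tracks(generate_truth(cfg), cfg), cfg)
#' dim(mov$stacks$pold[[1]])
#' @export
render_movie <- function(locs, config, background = 100,
                         amplitude_scale = 1, poisson_noise = TRUE,
                         channels = CHANNELS) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  nx <- cfg$field_size_px[1]; ny <- cfg$field_size_px[2]
  px <- cfg$pixel_size_nm
  sig <- cfg$psf_sigma_px
  half <- ceiling(4 * sig)
  out_of_field <- locs$x_nm < 0 | locs$x_nm >= nx * px |
    locs$y_nm < 0 | locs$y_nm >= ny * px
  if (any(out_of_field)) {
    warnf("%d localization(s) outside the field of view were clipped",
          sum(out_of_field))
    locs <- locs[!out_of_field, , drop = FALSE]
  }
  local_seed(child_seed(cfg$seed, "render"), {
    stacks <- list(); times <- list()
    for (ch in channels) {
      sel <- locs[locs$channel == ch, , drop = FALSE]
      fr_times <- frame_times(0:(cfg$movie_length_frames - 1L), ch,
                              cfg$frame_interval_s)
      stack <- vector("list", cfg$movie_length_frames)
      for (k in 0:(cfg$movie_length_frames - 1L)) {
        img <- matrix(background, nx, ny)
        frame_locs <- sel[sel$frame == k, , drop = FALSE]
        for (i in seq_len(nrow(frame_locs))) {
          # pixel centers at (j - 0.5) * px for 1-based pixel j
          x0 <- frame_locs$x_nm[i] / px + 0.5
          y0 <- frame_locs$y_nm[i] / px + 0.5
          amp <- frame_locs$intensity[i] * amplitude_scale
          jx <- max(1L, floor(x0 - half)):min(nx, ceiling(x0 + half))
          jy <- max(1L, floor(y0 - half)):min(ny, ceiling(y0 + half))
          gx <- exp(-(jx - x0)^2 / (2 * sig^2))
          gy <- exp(-(jy - y0)^2 / (2 * sig^2))
          img[jx, jy] <- img[jx, jy] + amp * outer(gx, gy)
        }
        if (poisson_noise)
          img <- matrix(stats::rpois(length(img), img), nx, ny)
        stack[[k + 1L]] <- pmin(img, 65535)
      }
      stacks[[ch]] <- stack
      times[[ch]] <- fr_times
    }
    structure(list(stacks = stacks, frame_times = times,
                   pixel_size_nm = px, config = cfg),
              class = "smt_movie")
  })
}

#' Write or read a rendered movie as multi-page TIFF plus JSON sidecar
#'
#' One 16-bit multi-page TIFF per channel (`<prefix>_<channel>.tif`) and a
#' JSON sidecar (`<prefix>_meta.json`) recording frame times, pixel size,
#' and channel order.
#'
#' @param movie An `smt_movie` from [render_movie()].
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return `write_movie` returns the sidecar path invisibly; `read_movie`
#'   returns an `smt_movie`-shaped list.
#' @export
write_movie <- function(movie, dir, prefix = "movie") {
  stopifnot(inherits(movie, "smt_movie"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in names(movie$stacks)) {
    # tiff expects [row, col] in [0, 1]; rows = y for conventional display
    pages <- lapply(movie$stacks[[ch]], function(m) t(m) / 65535)
    tiff::writeTIFF(pages, file.path(dir, sprintf("%s_%s.tif", prefix, ch)),
                    bits.per.sample = 16L)
  }
  meta <- list(channels = names(movie$stacks),
               frame_times_s = movie$frame_times,
               pixel_size_nm = movie$pixel_size_nm,
               field_size_px = dim(movie$stacks[[1]][[1]]))
  path <- file.path(dir, sprintf("%s_meta.json", prefix))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(dir, prefix = "movie") {
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_meta.json", prefix)),
                              simplifyVector = TRUE)
  stacks <- list()
  for (ch in meta$channels) {
    pages <- tiff::readTIFF(file.path(dir, sprintf("%s_%s.tif", prefix, ch)),
                            all = TRUE)
    stacks[[ch]] <- lapply(pages, function(m) t(m) * 65535)
  }
  structure(list(stacks = stacks, frame_times = meta$frame_times_s,
                 pixel_size_nm = meta$pixel_size_nm, config = NULL),
            class = "smt_movie")
}
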