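#' Localize single-molecule spots in one frame by 2D Gaussian fitting
#'
#' Detects candidate spots as local intensity maxima above a threshold and
#' refines each to sub-pixel precision by least-squares fitting of a 2D
#' Gaussian PSF model `b + A * exp(-((x-x0)^2 + (y-y0)^2) / (2 sigma^2))`
#' in a local window. Candidates whose fit fails to converge, whose fitted
#' width leaves `sigma_bounds_px`, whose amplitude is not positive, or
#' whose center leaves the window are rejected; duplicate fits converging
#' to the same position keep the brighter spot.
#'
#' @param image Matrix of pixel counts, indexed `[x, y]`; must be finite
#'   and nonnegative.
#' @param detect_threshold Absolute intensity a candidate local maximum
#'   must exceed; default `median(image) + 5 * mad(image)`.
#' @param psf_sigma_px Initial PSF width guess (px).
#' @param window_halfwidth Half-width (px) of the square fit window.
#' @param sigma_bounds_px Acceptable fitted width range (px).
#' @param pixel_size_nm Pixel size, for nm output columns.
#' @return Data frame with one row per accepted spot: `x_px`, `y_px`
#'   (continuous, origin at the field corner so pixel i spans
#'   `[i-1, i)`), `x_nm`, `y_nm`, `intensity` (fitted amplitude),
#'   `sigma_nm`, `background`, `rss`.
#' @examples
#' img <- matrix(10, 32, 32)
#' img[14:20, 14:20] <- img[14:20, 14:20] +
#'   500 * exp(-((14:20 - 16.8)^2 %o% rep(1, 7) +
#'               rep(1, 7) %o% (14:20 - 17.2)^2) / (2 * 1.5^2))
#' localize_frame(img, detect_threshold = 100)
#' @export
localize_frame <- function(image, detect_threshold = NULL,
                           psf_sigma_px = 1.5, window_halfwidth = 3L,
                           sigma_bounds_px = c(0.5, 4),
                           pixel_size_nm = 84) {
  if (!is.matrix(image) || any(!is.finite(image)))
    stopf("image must be a finite numeric matrix")
  if (any(image < 0)) stopf("image must be nonnegative")
  if (is.null(detect_threshold))
    detect_threshold <- stats::median(image) + 5 * stats::mad(image)
  cand <- local_maxima(image, detect_threshold)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      x_nm = numeric(0), y_nm = numeric(0),
                      intensity = numeric(0), sigma_nm = numeric(0),
                      background = numeric(0), rss = numeric(0))
  if (nrow(cand) == 0L) return(empty)
  h <- window_halfwidth
  nx <- nrow(image); ny <- ncol(image)
  fits <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    cx <- as.vector(cand[i, 1]); cy <- as.vector(cand[i, 2])
    jx <- max(1L, cx - h):min(nx, cx + h)
    jy <- max(1L, cy - h):min(ny, cy + h)
    w <- image[jx, jy, drop = FALSE]
    df <- data.frame(x = rep(jx - 0.5, times = length(jy)),
                     y = rep(jy - 0.5, each = length(jx)),
                     z = as.vector(w))
    b0 <- min(df$z); a0 <- max(df$z) - b0
    fit <- tryCatch(
      minpack.lm::nlsLM(
        z ~ b + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)),
        data = df,
        start = list(b = b0, A = a0, x0 = cx - 0.5, y0 = cy - 0.5,
                     s = psf_sigma_px),
        lower = c(0, 0, min(jx) - 1, min(jy) - 1, sigma_bounds_px[1] / 2),
        upper = c(Inf, Inf, max(jx), max(jy), sigma_bounds_px[2] * 2),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    if (any(!is.finite(cf))) next
    if (cf["s"] < sigma_bounds_px[1] || cf["s"] > sigma_bounds_px[2]) next
    if (cf["A"] <= 0) next
    if (cf["x0"] < min(jx) - 1 || cf["x0"] > max(jx) ||
        cf["y0"] < min(jy) - 1 || cf["y0"] > max(jy)) next
    fits[[i]] <- data.frame(
      x_px = unname(cf["x0"]), y_px = unname(cf["y0"]),
      intensity = unname(cf["A"]), sigma_px = unname(cf["s"]),
      background = unname(cf["b"]), rss = sum(stats::resid(fit)^2))
  }
  fits <- fits[!vapply(fits, is.null, TRUE)]
  if (!length(fits)) return(empty)
  out <- do.call(rbind, fits)
  out <- dedupe_spots(out, min_separation_px = 1)
  data.frame(x_px = out$x_px, y_px = out$y_px,
             x_nm = out$x_px * pixel_size_nm,
             y_nm = out$y_px * pixel_size_nm,
             intensity = out$intensity,
             sigma_nm = out$sigma_px * pixel_size_nm,
             background = out$background, rss = out$rss)
}

# Strict local maxima above a threshold (8-neighborhood), with interior
# margin of 1 px. Returns a matrix of (x, y) 1-based pixel indices.
local_maxima <- function(image, threshold) {
  nx <- nrow(image); ny <- ncol(image)
  if (nx < 3L || ny < 3L) return(matrix(integer(0), 0, 2))
  core <- image[2:(nx - 1), 2:(ny - 1)]
  is_max <- core > threshold
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- image[(2 + dx):(nx - 1 + dx), (2 + dy):(ny - 1 + dy)]
    # > for neighbors already scanned (lexicographic), >= for the rest:
    # exactly one pixel of a tied plateau survives
    is_max <- is_max & if (dx < 0 || (dx == 0 && dy < 0)) core > nb
    else core >= nb
  }
  ij <- which(is_max, arr.ind = TRUE)
  cbind(ij[, 1] + 1L, ij[, 2] + 1L)
}

dedupe_spots <- function(spots, min_separation_px = 1) {
  o <- order(-spots$intensity)
  spots <- spots[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(spots))
  for (i in seq_len(nrow(spots))) {
    if (!keep[i]) next
    if (i < nrow(spots)) {
      j <- (i + 1):nrow(spots)
      d2 <- (spots$x_px[j] - spots$x_px[i])^2 +
        (spots$y_px[j] - spots$y_px[i])^2
      keep[j][d2 < min_separation_px^2] <- FALSE
    }
  }
  spots[keep, , drop = FALSE]
}

#' Localize and track a rendered movie
#'
#' Runs [localize_frame()] on every frame of each channel stack and links
#' the localizations with [link_tracks()], returning per-channel track
#' sets merged into one `smt_tracks` object with channel labels.
#'
#' @param movie An `smt_movie` (from [render_movie()] or [read_movie()]).
#' @param frame_interval_s Per-channel frame interval (s).
#' @param ... Passed to [localize_frame()].
#' @inheritParams link_tracks
#' @return An `smt_tracks` object spanning both channels.
#' @export
track_movie <- function(movie, frame_interval_s = 1.34,
                        d_max_um2_s = 0.05, max_gap_s = 5, ...) {
  px <- movie$pixel_size_nm
  all_tracks <- list(); all_locs <- list()
  offset <- 0L
  for (ch in names(movie$stacks)) {
    stack <- movie$stacks[[ch]]
    times <- movie$frame_times[[ch]]
    locs <- list()
    for (k in seq_along(stack)) {
      f <- localize_frame(stack[[k]], pixel_size_nm = px, ...)
      if (nrow(f))
        locs[[k]] <- data.frame(channel = ch, frame = k - 1L,
                                t_s = times[k], x_nm = f$x_nm,
                                y_nm = f$y_nm, intensity = f$intensity)
    }
    locs <- do.call(rbind, locs)
    if (is.null(locs)) next
    trk <- link_tracks(locs, d_max_um2_s, max_gap_s, frame_interval_s,
                       n_frames = length(stack))
    tl <- track_locs(trk)
    tl$track_id <- tl$track_id + offset
    sm <- as.data.frame(trk)
    sm$track_id <- sm$track_id + offset
    offset <- max(c(offset, sm$track_id))
    all_tracks[[ch]] <- sm
    all_locs[[ch]] <- tl
  }
  if (!length(all_tracks))
    return(empty_tracks(empty_loc_table(), frame_interval_s))
  out <- do.call(rbind, all_tracks)
  rownames(out) <- NULL
  locs <- do.call(rbind, all_locs)
  attr(locs, "pixel_size_nm") <- px
  new_tracks(out, locs, frame_interval_s)
}
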