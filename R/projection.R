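#' 2D projection map of binding-event positions
#'
#' Bins the time-averaged position of every track onto the native pixel
#' grid, producing the event-count map used for display and as input to
#' hub detection. The sum over the map equals the number of tracks.
#'
#' @param tracks An `smt_tracks` object (or any data frame with `mean_x`,
#'   `mean_y` in nm).
#' @param pixel_size_nm Grid pixel size (nm).
#' @param dims_px Grid size in pixels, `c(nx, ny)`.
#' @return An integer matrix of dimension `c(nx, ny)`; entry `[i, j]`
#'   counts tracks with `floor(mean_x / pixel) == i - 1` and likewise in y.
#' @examples
#' trk <- data.frame(mean_x = c(10, 100, 100), mean_y = c(10, 10, 10))
#' m <- build_projection_map(trk, pixel_size_nm = 84, dims_px = c(4, 4))
#' sum(m) == 3
#' @export
build_projection_map <- function(tracks, pixel_size_nm = 84,
                                 dims_px = c(512L, 512L)) {
  x <- tracks$mean_x; y <- tracks$mean_y
  if (length(x) == 0L)
    return(matrix(0L, dims_px[1], dims_px[2]))
  ix <- floor(x / pixel_size_nm)
  iy <- floor(y / pixel_size_nm)
  if (any(ix < 0 | ix >= dims_px[1] | iy < 0 | iy >= dims_px[2]))
    stopf("track positions fall outside the %d x %d px grid",
          dims_px[1], dims_px[2])
  m <- matrix(0L, dims_px[1], dims_px[2])
  tab <- table(ix + dims_px[1] * iy)
  m[as.integer(names(tab)) + 1L] <- as.integer(tab)
  m
}
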