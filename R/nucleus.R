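#' Nuclear region of interest
#'
#' A nucleus ROI is a closed simple polygon in nm coordinates (typically
#' traced from the 2D projection of the summed clamp-channel fluorescence).
#' Points on the boundary count as inside.
#'
#' @param vertices_nm Two-column matrix of polygon vertices (nm), open or
#'   closed (first vertex repeated); stored closed.
#' @param pixel_size_nm Pixel size (nm) of the native grid, recorded for
#'   conversions.
#' @return An object of class `nucleus_roi` with elements `vertices_nm`
#'   (closed polygon), `area_nm2`, `pixel_size_nm`.
#' @examples
#' roi <- ellipse_roi(c(4000, 3000), center = c(5000, 5000))
#' roi$area_nm2 / (pi * 4000 * 3000)  # close to 1
#' @export
nucleus_roi <- function(vertices_nm, pixel_size_nm = 84) {
  v <- as.matrix(vertices_nm)
  if (ncol(v) != 2L || nrow(v) < 3L) stopf("polygon needs >= 3 x,y vertices")
  if (!all(v[1, ] == v[nrow(v), ])) v <- rbind(v, v[1, ])
  n <- nrow(v) - 1L
  area <- abs(sum(v[1:n, 1] * v[2:(n + 1), 2] -
                    v[2:(n + 1), 1] * v[1:n, 2])) / 2
  if (area <= 0) stopf("degenerate ROI: zero area")
  structure(list(vertices_nm = v, area_nm2 = area,
                 pixel_size_nm = pixel_size_nm),
            class = "nucleus_roi")
}

#' @rdname nucleus_roi
#' @param semiaxes_nm Ellipse semi-axes (nm).
#' @param center Ellipse center (nm).
#' @param n_vertices Number of polygon vertices approximating the ellipse.
#' @export
ellipse_roi <- function(semiaxes_nm, center = semiaxes_nm, n_vertices = 96L,
                        pixel_size_nm = 84) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  nucleus_roi(cbind(center[1] + semiaxes_nm[1] * cos(th),
                    center[2] + semiaxes_nm[2] * sin(th)),
              pixel_size_nm)
}

#' Test points against a nucleus ROI
#'
#' Inside-or-on-boundary convention: a point exactly on a polygon edge or
#' vertex is inside.
#'
#' @param roi A `nucleus_roi`.
#' @param x_nm,y_nm Point coordinates (nm).
#' @return Logical vector.
#' @export
roi_contains <- function(roi, x_nm, y_nm) {
  stopifnot(inherits(roi, "nucleus_roi"))
  pts <- cbind(x_nm, y_nm)
  if (nrow(pts) == 0L) return(logical(0))
  inside <- mgcv::in.out(roi$vertices_nm, pts)
  border <- !inside & on_boundary(roi$vertices_nm, pts)
  inside | border
}

# Points lying on a polygon edge (within a small relative tolerance).
on_boundary <- function(poly, pts, tol = 1e-9) {
  scale <- max(abs(poly)) + 1
  eps <- tol * scale
  out <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    tpar <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    tpar <- pmin(pmax(tpar, 0), 1)
    dx <- a[1] + tpar * ab[1] - pts[, 1]
    dy <- a[2] + tpar * ab[2] - pts[, 2]
    out <- out | (dx * dx + dy * dy <= eps^2)
  }
  out
}

#' Keep tracks whose mean position lies inside the nucleus
#'
#' @param tracks An `smt_tracks` object.
#' @param roi A `nucleus_roi`.
#' @return The filtered `smt_tracks` (localizations of removed tracks are
#'   dropped from the attached table as well).
#' @export
filter_nuclear_tracks <- function(tracks, roi) {
  keep <- roi_contains(roi, tracks$mean_x, tracks$mean_y)
  locs <- track_locs(tracks)
  kept <- as.data.frame(tracks)[keep, , drop = FALSE]
  rownames(kept) <- NULL
  keykeep <- paste(kept$channel, kept$track_id)
  lockeep <- paste(locs$channel, locs$track_id) %in% keykeep
  new_tracks(kept, locs[lockeep, , drop = FALSE],
             attr(tracks, "frame_interval_s"))
}

#' Draw uniform points inside a nucleus ROI
#'
#' Rejection sampling from the ROI bounding box.
#'
#' @param roi A `nucleus_roi`.
#' @param n Number of points.
#' @return A two-column matrix (nm).
#' @keywords internal
sample_in_roi <- function(roi, n) {
  v <- roi$vertices_nm
  bbox <- c(min(v[, 1]), max(v[, 1]), min(v[, 2]), max(v[, 2]))
  frac <- roi$area_nm2 / ((bbox[2] - bbox[1]) * (bbox[4] - bbox[3]))
  if (frac <= 0) stopf("degenerate ROI")
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) / frac * 1.2) + 16L
    cand <- cbind(stats::runif(m, bbox[1], bbox[2]),
                  stats::runif(m, bbox[3], bbox[4]))
    ok <- mgcv::in.out(v, cand)
    out <- rbind(out, cand[ok, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' @export
print.nucleus_roi <- function(x, ...) {
  cat(sprintf("Nucleus ROI: %d vertices, area %.3g um^2\n",
              nrow(x$vertices_nm) - 1L, x$area_nm2 / 1e6))
  invisible(x)
}
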