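#' Movie container
#'
#' A time-ordered stack of 2-D intensity frames with physical pixel size.
#'
#' @param data Numeric array `ny x nx x n_frames` (arbitrary units).
#' @param pixel_size Pixel size, um/pixel.
#' @param frame_rate Frame rate, Hz.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(data, pixel_size, frame_rate) {
  if (length(dim(data)) != 3)
    stop("data must be a ny x nx x n_frames array", call. = FALSE)
  if (pixel_size <= 0 || frame_rate <= 0)
    stop("pixel_size and frame_rate must be positive", call. = FALSE)
  structure(list(data = data, pixel_size = pixel_size,
                 frame_rate = frame_rate), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("frame_stack: %d x %d px, %d frames, %.3f um/px, %g Hz\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_rate))
  invisible(x)
}

#' Region of interest over a soma
#'
#' A circular or annular region in physical (um) coordinates. Annular ROIs
#' exclude the nuclear disk, where cytosolic indicator is absent. A pixel
#' belongs to the mask when its center lies inside the region
#' (half-open: `inner_radius <= d < outer_radius`).
#'
#' @param center_x,center_y ROI center, um from the image origin (the
#'   corner of pixel (0, 0); pixel j has its center at `(j + 0.5) *
#'   pixel_size`, 0-based).
#' @param outer_radius Outer radius, um.
#' @param inner_radius Inner radius, um (0 for circular ROIs).
#' @param kind `"circular"` or `"annular"`; inferred from `inner_radius`
#'   when missing.
#' @return An object of class `roi`.
#' @export
roi <- function(center_x, center_y, outer_radius, inner_radius = 0,
                kind = if (inner_radius > 0) "annular" else "circular") {
  kind <- match.arg(kind, c("circular", "annular"))
  if (inner_radius < 0 || outer_radius <= inner_radius)
    stop("need 0 <= inner_radius < outer_radius", call. = FALSE)
  if (kind == "circular" && inner_radius > 0)
    stop("circular ROI must have inner_radius 0", call. = FALSE)
  structure(list(center_x = center_x, center_y = center_y,
                 outer_radius = outer_radius, inner_radius = inner_radius,
                 kind = kind), class = "roi")
}

#' A set of ROIs tied to an image geometry
#'
#' @param rois List of [roi()] objects.
#' @param pixel_size Pixel size, um/pixel.
#' @param image_size Image side, pixels (square images).
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(rois, pixel_size, image_size) {
  stopifnot(all(vapply(rois, inherits, logical(1), "roi")))
  fov <- image_size * pixel_size
  for (r in rois) {
    if (r$center_x - r$outer_radius < 0 || r$center_y - r$outer_radius < 0 ||
        r$center_x + r$outer_radius > fov || r$center_y + r$outer_radius > fov)
      stop("ROI extends beyond image bounds", call. = FALSE)
  }
  structure(list(rois = rois, pixel_size = pixel_size,
                 image_size = as.integer(image_size)), class = "roi_set")
}

## Linear (column-major) pixel indices of an annulus/disk in an ny x nx
## image. Pixel centers are at ((col - 0.5) * px, (row - 0.5) * px) um,
## 1-based rows/cols; membership is half-open in radius.
annulus_pixels <- function(cx, cy, outer_r, inner_r, pixel_size, ny, nx) {
  jmin <- max(1L, floor((cx - outer_r) / pixel_size))
  jmax <- min(nx, ceiling((cx + outer_r) / pixel_size) + 1L)
  imin <- max(1L, floor((cy - outer_r) / pixel_size))
  imax <- min(ny, ceiling((cy + outer_r) / pixel_size) + 1L)
  if (jmin > jmax || imin > imax) return(integer(0))
  jj <- jmin:jmax; ii <- imin:imax
  xs <- (jj - 0.5) * pixel_size
  ys <- (ii - 0.5) * pixel_size
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  sel <- d2 < outer_r^2 & d2 >= inner_r^2
  idx <- which(sel)
  row <- ii[(idx - 1) %% length(ii) + 1]
  col <- jj[(idx - 1) %/% length(ii) + 1]
  (col - 1L) * ny + row
}

#' Pixel mask of an ROI
#' @param x A [roi()].
#' @param pixel_size Pixel size, um/pixel.
#' @param ny,nx Image dimensions, pixels.
#' @return Integer vector of column-major linear pixel indices.
#' @export
roi_mask <- function(x, pixel_size, ny, nx = ny) {
  annulus_pixels(x$center_x, x$center_y, x$outer_radius, x$inner_radius,
                 pixel_size, ny, nx)
}

## Full soma disk (outer radius, annular interior included) — used when
## excluding somata from neuropil regions.
soma_disk_mask <- function(x, pixel_size, ny, nx = ny) {
  annulus_pixels(x$center_x, x$center_y, x$outer_radius, 0,
                 pixel_size, ny, nx)
}

#' Extract the mean-fluorescence trace of an ROI
#'
#' One value per frame: the arithmetic mean over all pixels of the ROI
#' mask.
#'
#' @param stack A [frame_stack()].
#' @param x A [roi()].
#' @return Numeric vector of length `n_frames`.
#' @export
extract_trace <- function(stack, x) {
  d <- dim(stack$data)
  idx <- roi_mask(x, stack$pixel_size, d[1], d[2])
  if (length(idx) == 0)
    stop("ROI mask is empty at this pixel size", call. = FALSE)
  mat <- matrix(stack$data, d[1] * d[2], d[3])
  colMeans(mat[idx, , drop = FALSE])
}

#' Neuropil trace around a cell
#'
#' Mean over all pixels within `radius` um of the cell center, excluding
#' the full soma disk of every ROI in the set (not only the cell's own).
#'
#' @param stack A [frame_stack()].
#' @param rois A [roi_set()].
#' @param cell_index Index of the cell in `rois$rois`.
#' @param radius Neuropil region radius, um (default 20).
#' @return Numeric vector of length `n_frames`.
#' @export
neuropil_trace <- function(stack, rois, cell_index, radius = 20) {
  d <- dim(stack$data)
  px <- stack$pixel_size
  cell <- rois$rois[[cell_index]]
  region <- annulus_pixels(cell$center_x, cell$center_y, radius, 0,
                           px, d[1], d[2])
  somata <- unlist(lapply(rois$rois, soma_disk_mask, pixel_size = px,
                          ny = d[1], nx = d[2]))
  idx <- setdiff(region, somata)
  if (length(idx) == 0)
    stop("neuropil region fully covered by somata for cell ", cell_index,
         call. = FALSE)
  mat <- matrix(stack$data, d[1] * d[2], d[3])
  colMeans(mat[idx, , drop = FALSE])
}

#' Neuropil-region pixel mask (somata excluded)
#' @inheritParams neuropil_trace
#' @return Integer vector of column-major linear pixel indices.
#' @export
neuropil_mask <- function(rois, cell_index, radius = 20,
                          ny = rois$image_size, nx = rois$image_size) {
  cell <- rois$rois[[cell_index]]
  region <- annulus_pixels(cell$center_x, cell$center_y, radius, 0,
                           rois$pixel_size, ny, nx)
  somata <- unlist(lapply(rois$rois, soma_disk_mask,
                          pixel_size = rois$pixel_size, ny = ny, nx = nx))
  setdiff(region, somata)
}

#' Choose annular vs circular ROI from the neuron's appearance
#'
#' Healthy cytosolic expression leaves the nucleus dark: when the central
#' (nuclear) disk of the time-averaged image is dimmer than 80% of the
#' surrounding ring, an annular ROI is placed, otherwise a circular one.
#' Pass `kind` to override the automatic rule.
#'
#' @param stack A [frame_stack()].
#' @param center_x,center_y Soma center, um.
#' @param soma_radius,nucleus_radius Soma and nucleus radii, um.
#' @param kind Optional manual override: `"circular"` or `"annular"`.
#' @param dark_center_ratio Threshold on center/ring mean brightness below
#'   which the center counts as a dark nucleus.
#' @return A [roi()].
#' @export
auto_roi <- function(stack, center_x, center_y, soma_radius,
                     nucleus_radius, kind = NULL,
                     dark_center_ratio = 0.8) {
  if (!is.null(kind))
    return(roi(center_x, center_y, soma_radius,
               if (kind == "annular") nucleus_radius else 0, kind))
  d <- dim(stack$data)
  avg <- rowMeans(matrix(stack$data, d[1] * d[2], d[3]))
  ctr <- annulus_pixels(center_x, center_y, nucleus_radius, 0,
                        stack$pixel_size, d[1], d[2])
  ring <- annulus_pixels(center_x, center_y, soma_radius, nucleus_radius,
                         stack$pixel_size, d[1], d[2])
  if (length(ctr) == 0 || length(ring) == 0)
    return(roi(center_x, center_y, soma_radius))
  annular <- mean(avg[ctr]) < dark_center_ratio * mean(avg[ring])
  roi(center_x, center_y, soma_radius,
      if (annular) nucleus_radius else 0)
}
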