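#' Segment ring-like somata in a single-channel image
#'
#' Reproducible stand-in for analyst-guided soma selection: a band-pass
#' (difference-of-Gaussians) filter at the expected soma scale highlights
#' soma-sized blobs, local maxima above a robust threshold seed candidate
#' cells, candidates closer than 1.5 soma radii are merged (brightest
#' wins), and centers are refined by an intensity-weighted centroid. Each
#' segment's mask is the nucleus-excluded annulus between
#' `nucleus_radius` and `soma_radius`. When `seeds` are supplied they
#' bypass detection and force one segment each.
#'
#' @param image Numeric matrix (single channel).
#' @param pixel_size Pixel size, um/pixel.
#' @param soma_radius,nucleus_radius Expected soma/nucleus radii, um.
#' @param seeds Optional data frame with `x`, `y` centers in um.
#' @param threshold_k Detection threshold in robust SDs (MAD) of the
#'   band-pass image above its median.
#' @return A list of `soma_segment` objects: `center_x`, `center_y` (um),
#'   `mask` (column-major pixel indices of the ring). Empty list when
#'   nothing is detected.
#' @export
segment_somata <- function(image, pixel_size, soma_radius = 6,
                           nucleus_radius = 3, seeds = NULL,
                           threshold_k = 3) {
  ny <- nrow(image); nx <- ncol(image)
  make_segment <- function(cx, cy) {
    structure(list(
      center_x = cx, center_y = cy,
      mask = annulus_pixels(cx, cy, soma_radius, nucleus_radius,
                            pixel_size, ny, nx)
    ), class = "soma_segment")
  }
  if (!is.null(seeds))
    return(lapply(seq_len(nrow(seeds)), function(i)
      make_segment(seeds$x[i], seeds$y[i])))

  r_px <- soma_radius / pixel_size
  ## band-pass at the soma scale; the background Gaussian is kept narrow
  ## (1.6 soma radii) so a bright neighbor's negative lobe cannot mask a
  ## dim cell
  g1 <- as.matrix(EBImage::gblur(image, sigma = r_px / 2))
  dog <- g1 - as.matrix(EBImage::gblur(image, sigma = 1.6 * r_px))
  thr <- stats::median(dog) + threshold_k * stats::mad(dog)
  brush_size <- 2 * floor(r_px / 2) + 1
  dil <- as.matrix(EBImage::dilate(
    dog, EBImage::makeBrush(brush_size, shape = "disc")))
  is_max <- dog >= dil & dog > thr
  idx <- which(is_max)
  if (!length(idx)) return(list())
  row <- (idx - 1) %% ny + 1
  col <- (idx - 1) %/% ny + 1
  ord <- order(dog[idx], decreasing = TRUE)
  row <- row[ord]; col <- col[ord]
  ## greedy suppression of maxima closer than 1.5 soma radii
  keep_r <- keep_c <- numeric(0)
  min_d2 <- (1.5 * r_px)^2
  for (i in seq_along(row)) {
    if (!length(keep_r) ||
        all((keep_r - row[i])^2 + (keep_c - col[i])^2 >= min_d2)) {
      keep_r <- c(keep_r, row[i]); keep_c <- c(keep_c, col[i])
    }
  }
  ## iterated intensity-weighted centroid on the background-subtracted
  ## smoothed image (symmetric for ring-shaped somata, so unbiased)
  g1bg <- pmax(g1 - stats::median(g1), 0)
  segs <- vector("list", length(keep_r))
  for (i in seq_along(keep_r)) {
    cx <- (keep_c[i] - 0.5) * pixel_size
    cy <- (keep_r[i] - 0.5) * pixel_size
    for (it in 1:3) {
      win <- annulus_pixels(cx, cy, soma_radius, 0, pixel_size, ny, nx)
      w <- g1bg[win]
      if (sum(w) == 0) break
      wr <- (win - 1) %% ny + 1
      wc <- (win - 1) %/% ny + 1
      cy <- (sum(w * wr) / sum(w) - 0.5) * pixel_size
      cx <- (sum(w * wc) / sum(w) - 0.5) * pixel_size
    }
    segs[[i]] <- make_segment(cx, cy)
  }
  ## drop segments whose ring leaves the image
  segs[vapply(segs, function(s) length(s$mask) > 0, logical(1))]
}

#' Mean somatic brightness of a segment
#'
#' @param segment A `soma_segment` from [segment_somata()].
#' @param image The image it was segmented from.
#' @return Mean of the ring-mask pixels (arbitrary units).
#' @export
somatic_brightness <- function(segment, image) {
  if (!length(segment$mask))
    stop("segment has an empty mask", call. = FALSE)
  mean(image[segment$mask])
}

#' Detect fluorescence-standard beads
#'
#' Beads are bright disks of known diameter; detection mirrors
#' [segment_somata()] at the bead scale with a disk (not ring) mask.
#'
#' @param bead_image Numeric matrix.
#' @param pixel_size Pixel size, um/pixel.
#' @param bead_diameter Bead diameter, um (default 3.8).
#' @param threshold_k Detection threshold in MADs.
#' @return Data frame with `x`, `y` (um) and `brightness` per bead.
#' @export
detect_beads <- function(bead_image, pixel_size, bead_diameter = 3.8,
                         threshold_k = 6) {
  r <- bead_diameter / 2
  segs <- segment_somata(bead_image, pixel_size, soma_radius = r,
                         nucleus_radius = r / 100,
                         threshold_k = threshold_k)
  ny <- nrow(bead_image); nx <- ncol(bead_image)
  if (!length(segs))
    return(data.frame(x = numeric(0), y = numeric(0),
                      brightness = numeric(0)))
  data.frame(
    x = vapply(segs, `[[`, numeric(1), "center_x"),
    y = vapply(segs, `[[`, numeric(1), "center_y"),
    brightness = vapply(segs, function(s) {
      disk <- annulus_pixels(s$center_x, s$center_y, r * 0.7, 0,
                             pixel_size, ny, nx)
      mean(bead_image[disk])
    }, numeric(1))
  )
}

#' Normalize somatic brightness by the bead standard
#'
#' Dividing by the mean detected bead brightness removes global
#' illumination/gain differences between imaging sessions exactly (both
#' cells and beads scale with excitation intensity).
#'
#' @param brightness_raw Numeric vector of raw somatic brightness values.
#' @param bead_image Bead-field image acquired under the same conditions.
#' @param pixel_size Pixel size, um/pixel.
#' @param bead_diameter Bead diameter, um.
#' @return Normalized (dimensionless) brightness values.
#' @export
bead_normalize <- function(brightness_raw, bead_image, pixel_size,
                           bead_diameter = 3.8) {
  beads <- detect_beads(bead_image, pixel_size, bead_diameter)
  if (nrow(beads) == 0)
    stop("no beads detected; cannot normalize", call. = FALSE)
  brightness_raw / mean(beads$brightness)
}

#' Fraction of reference-channel cells carrying the label
#'
#' Greedy one-to-one matching by nearest center distance: each red
#' (reference, pan-neuronal) soma is matched to at most one green
#' (labeled) soma within `match_radius`. The fraction is matched red
#' somata over all red somata.
#'
#' @param green_segments,red_segments Segment lists from
#'   [segment_somata()] (registered channels), or data frames with `x`,
#'   `y` columns in um.
#' @param match_radius Maximum center distance for a match, um (default:
#'   one soma radius, 6 um).
#' @return Fraction in [0, 1].
#' @export
colabel_fraction <- function(green_segments, red_segments,
                             match_radius = 6) {
  centers <- function(segs) {
    if (is.data.frame(segs)) return(segs[, c("x", "y")])
    data.frame(x = vapply(segs, `[[`, numeric(1), "center_x"),
               y = vapply(segs, `[[`, numeric(1), "center_y"))
  }
  g <- centers(green_segments)
  r <- centers(red_segments)
  if (nrow(r) == 0)
    stop("no reference (red) somata; fraction undefined", call. = FALSE)
  if (nrow(g) == 0) return(0)
  d <- sqrt(outer(r$x, g$x, "-")^2 + outer(r$y, g$y, "-")^2)
  pairs <- which(d <= match_radius, arr.ind = TRUE)
  if (!nrow(pairs)) return(0)
  ord <- order(d[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used_r <- logical(nrow(r)); used_g <- logical(nrow(g))
  matched <- 0L
  for (i in seq_len(nrow(pairs))) {
    ri <- pairs[i, 1]; gi <- pairs[i, 2]
    if (!used_r[ri] && !used_g[gi]) {
      used_r[ri] <- used_g[gi] <- TRUE
      matched <- matched + 1L
    }
  }
  matched / nrow(r)
}

#' Box-and-whisker statistics
#'
#' Median and quartiles by linear interpolation between order statistics
#' (R's default quantile rule, type 7; stated because it changes values at
#' small n). Whiskers extend at most 1.5 x IQR beyond the quartiles
#' (i.e. whisker length 150% of the 25th-to-75th-percentile distance) but
#' are clamped to the most extreme sample inside that range; samples
#' beyond the whiskers are listed as outliers.
#'
#' @param values Numeric vector (>= 1 value).
#' @return A list with `median`, `q25`, `q75`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @export
box_stats <- function(values) {
  if (!length(values)) stop("need at least one value", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  list(median = q[2], q25 = q[1], q75 = q[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(values[values < lo_fence | values > hi_fence]))
}
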