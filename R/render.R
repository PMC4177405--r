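#' Place non-overlapping somata in a field of view
#'
#' Rejection sampling of cell centers with a minimum pairwise distance of
#' one soma diameter plus a 1 um margin; errors out when the requested
#' density cannot be placed within a bounded number of retries.
#'
#' @param scene A [scene_model()].
#' @param seed Optional integer seed.
#' @param max_tries Retries per cell before giving up.
#' @return Data frame with `x`, `y` centers in um.
#' @export
place_cells <- function(scene, seed = NULL, max_tries = 5000) {
  if (!is.null(seed)) set.seed(seed)
  fov <- scene$field_of_view
  r <- scene$soma_radius
  min_d <- 2 * r + 1
  xs <- ys <- numeric(0)
  for (i in seq_len(scene$n_cells)) {
    ok <- FALSE
    for (k in seq_len(max_tries)) {
      x <- stats::runif(1, r + 1, fov - r - 1)
      y <- stats::runif(1, r + 1, fov - r - 1)
      if (!length(xs) || all((xs - x)^2 + (ys - y)^2 >= min_d^2)) {
        xs <- c(xs, x); ys <- c(ys, y); ok <- TRUE; break
      }
    }
    if (!ok)
      stop("could not place ", scene$n_cells,
           " non-overlapping somata in this field of view", call. = FALSE)
  }
  data.frame(x = xs, y = ys)
}

## Smooth positive spatial texture with mean 1: low-pass-filtered white
## noise, rescaled. `amp` is the relative fluctuation amplitude.
smooth_texture <- function(ny, nx, sigma_px, amp = 0.3) {
  z <- matrix(stats::rnorm(ny * nx), ny, nx)
  z <- as.matrix(EBImage::gblur(z, sigma = sigma_px))
  z <- (z - mean(z)) / stats::sd(z)
  pmax(1 + amp * z, 0.05)
}

#' Render a simulated session as a movie
#'
#' Draws each soma as a ring (bright cytosol, dark nucleus at 25%
#' brightness), a spatially smooth neuropil field everywhere whose temporal
#' profile is the simulation's neuropil trace, contamination of somatic
#' pixels by `contamination_ratio_true` times the mean-field neuropil
#' trace, and optional per-pixel Gaussian noise.
#'
#' @param sim A `sim_population` from [simulate_population()].
#' @param seed Optional integer seed for the texture and pixel noise.
#' @param texture_amp Relative amplitude of the neuropil spatial texture.
#' @return A list with `stack` (a [frame_stack()]), `rois` (the ground
#'   truth [roi_set()], annular), and `centers` (um).
#' @export
render_movie <- function(sim, seed = NULL, texture_amp = 0.2) {
  if (!is.null(seed)) set.seed(seed)
  scene <- sim$scene
  n <- scene$image_size
  px <- scene$field_of_view / n
  centers <- place_cells(scene)
  gt <- sim$ground_truth
  nf <- ncol(sim$measured)
  npil <- gt$neuropil
  r_true <- scene$contamination_ratio_true

  s <- smooth_texture(n, n, sigma_px = scene$soma_radius / px,
                      amp = texture_amp)
  M <- outer(as.vector(s), npil)           # background field, npix x nf
  rois <- vector("list", scene$n_cells)
  for (i in seq_len(scene$n_cells)) {
    ring <- annulus_pixels(centers$x[i], centers$y[i], scene$soma_radius,
                           scene$nucleus_radius, px, n, n)
    nuc <- annulus_pixels(centers$x[i], centers$y[i], scene$nucleus_radius,
                          0, px, n, n)
    cyto_i <- gt$cyto[i, ]
    ## somatic contamination integrates out-of-focus neuropil over a wide
    ## volume, so it follows the mean-field neuropil trace, not the local
    ## texture — rendering then inverts exactly to the measurement model
    M[ring, ] <- matrix(cyto_i + r_true * npil, length(ring), nf,
                        byrow = TRUE)
    if (length(nuc))
      M[nuc, ] <- matrix(0.25 * cyto_i + r_true * npil, length(nuc), nf,
                         byrow = TRUE)
    rois[[i]] <- roi(centers$x[i], centers$y[i], scene$soma_radius,
                     scene$nucleus_radius)
  }
  if (scene$noise_sd_frac > 0)
    M <- M + stats::rnorm(length(M),
                          sd = scene$noise_sd_frac * mean(gt$baselines))
  stack <- frame_stack(array(M, c(n, n, nf)), pixel_size = px,
                       frame_rate = sim$protocol$frame_rate)
  list(stack = stack, rois = roi_set(rois, px, n), centers = centers)
}

#' Generate a two-channel histology image with ground truth
#'
#' Emulates a confocal section of indicator-expressing cortex
#' counterstained for the pan-neuronal nuclear marker: the red channel
#' holds all somata as filled disks, the green channel holds a labeled
#' subset drawn as nucleus-excluded rings with per-cell brightness sampled
#' log-normally, and a separate bead field holds fluorescence-standard
#' beads of known diameter and brightness.
#'
#' @param n_cells Number of somata.
#' @param labeled_fraction Fraction of somata carrying the green label.
#' @param image_size Image side, pixels.
#' @param pixel_size Pixel size, um/pixel.
#' @param soma_radius,nucleus_radius Soma/nucleus radii, um.
#' @param brightness_mean Mean green somatic brightness (arbitrary units).
#' @param brightness_cv Coefficient of variation of green brightness
#'   across cells (log-normal).
#' @param n_beads Number of beads in the bead field.
#' @param bead_diameter Bead diameter, um (fluorescent-standard beads are
#'   3.8 um).
#' @param bead_brightness Bead brightness (arbitrary units).
#' @param illumination Global multiplicative illumination factor applied to
#'   the green channel and the bead field alike (session-to-session
#'   excitation differences).
#' @param noise_sd Additive Gaussian pixel noise SD (arbitrary units).
#' @param seed Integer seed.
#' @return A list with matrices `green`, `red`, `beads`, the `truth` data
#'   frame (`cell`, `x`, `y` in um, `labeled`, `brightness`), and
#'   `pixel_size`.
#' @export
generate_histology_image <- function(n_cells = 80, labeled_fraction = 0.6,
                                     image_size = 512, pixel_size = 0.5,
                                     soma_radius = 6, nucleus_radius = 3,
                                     brightness_mean = 1, brightness_cv = 0.5,
                                     n_beads = 25, bead_diameter = 3.8,
                                     bead_brightness = 2,
                                     illumination = 1,
                                     noise_sd = 0.02, seed = 1) {
  if (labeled_fraction < 0 || labeled_fraction > 1)
    stop("labeled_fraction must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  scene <- scene_model(field_of_view = image_size * pixel_size,
                       image_size = image_size, n_cells = n_cells,
                       soma_radius = soma_radius,
                       nucleus_radius = nucleus_radius)
  centers <- place_cells(scene)
  labeled <- stats::runif(n_cells) < labeled_fraction
  sdlog <- sqrt(log(1 + brightness_cv^2))
  brightness <- brightness_mean * stats::rlnorm(n_cells, -sdlog^2 / 2, sdlog)

  n <- image_size
  green <- matrix(0.02, n, n)
  red <- matrix(0.05, n, n)
  for (i in seq_len(n_cells)) {
    disk <- annulus_pixels(centers$x[i], centers$y[i], soma_radius, 0,
                           pixel_size, n, n)
    red[disk] <- 1
    if (labeled[i]) {
      ring <- annulus_pixels(centers$x[i], centers$y[i], soma_radius,
                             nucleus_radius, pixel_size, n, n)
      nuc <- annulus_pixels(centers$x[i], centers$y[i], nucleus_radius, 0,
                            pixel_size, n, n)
      green[ring] <- brightness[i]
      green[nuc] <- 0.1 * brightness[i]
    }
  }
  bead_scene <- scene_model(field_of_view = image_size * pixel_size,
                            image_size = image_size, n_cells = n_beads,
                            soma_radius = bead_diameter / 2,
                            nucleus_radius = bead_diameter / 4)
  bead_centers <- place_cells(bead_scene)
  beads <- matrix(0.01, n, n)
  for (i in seq_len(n_beads)) {
    disk <- annulus_pixels(bead_centers$x[i], bead_centers$y[i],
                           bead_diameter / 2, 0, pixel_size, n, n)
    beads[disk] <- bead_brightness
  }
  green <- illumination * green + stats::rnorm(n * n, sd = noise_sd)
  red <- red + stats::rnorm(n * n, sd = noise_sd)
  beads <- illumination * beads + stats::rnorm(n * n, sd = noise_sd)
  list(green = green, red = red, beads = beads,
       truth = data.frame(cell = seq_len(n_cells), x = centers$x,
                          y = centers$y, labeled = labeled,
                          brightness = brightness),
       pixel_size = pixel_size)
}
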