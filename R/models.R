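#' Indicator kinetics model
#'
#' Parameters of the per-spike fluorescence kernel: a difference of
#' exponentials with time-to-peak governed by `rise_time` and a post-peak
#' half-decay equal to `decay_half_time`. The decay time constant is solved
#' numerically so that the kernel's measured half-decay matches
#' `decay_half_time` exactly (see [fluorescence_kernel()]).
#'
#' @param rise_time Rise time constant, seconds; must be smaller than
#'   `decay_half_time`.
#' @param decay_half_time Post-peak half-decay time of the unitary
#'   transient, seconds.
#' @param amplitude_per_spike Peak dF/F contribution of a single spike.
#' @param baseline_fluorescence Resting fluorescence, arbitrary units.
#' @param label Indicator name (free text).
#' @return An object of class `kinetics_model`.
#' @seealso [indicator_preset()] for GCaMP6f-like / GCaMP6s-like presets.
#' @export
kinetics_model <- function(rise_time, decay_half_time, amplitude_per_spike,
                           baseline_fluorescence = 100, label = "custom") {
  if (rise_time <= 0 || decay_half_time <= 0)
    stop("kinetics times must be positive", call. = FALSE)
  if (rise_time >= decay_half_time)
    stop("rise_time must be smaller than decay_half_time", call. = FALSE)
  if (amplitude_per_spike <= 0)
    stop("amplitude_per_spike must be positive", call. = FALSE)
  if (baseline_fluorescence <= 0)
    stop("baseline_fluorescence must be positive", call. = FALSE)
  structure(list(
    rise_time = rise_time,
    decay_half_time = decay_half_time,
    amplitude_per_spike = amplitude_per_spike,
    baseline_fluorescence = baseline_fluorescence,
    label = label
  ), class = "kinetics_model")
}

#' Kinetics presets for fast and slow indicators
#'
#' `"fast"` emulates a GCaMP6f-class indicator (half-decay 0.14 s),
#' `"slow"` a GCaMP6s-class indicator (half-decay 0.51 s). These are
#' simulator parameters chosen within the range of published in-tissue
#' measurements, not claims about any particular preparation.
#'
#' @param indicator `"fast"` or `"slow"`.
#' @param baseline_fluorescence Resting fluorescence, arbitrary units.
#' @return A [kinetics_model()].
#' @export
indicator_preset <- function(indicator = c("fast", "slow"),
                             baseline_fluorescence = 100) {
  indicator <- match.arg(indicator)
  if (indicator == "fast")
    kinetics_model(rise_time = 0.02, decay_half_time = 0.14,
                   amplitude_per_spike = 0.19,
                   baseline_fluorescence = baseline_fluorescence,
                   label = "fast")
  else
    kinetics_model(rise_time = 0.08, decay_half_time = 0.51,
                   amplitude_per_spike = 0.25,
                   baseline_fluorescence = baseline_fluorescence,
                   label = "slow")
}

#' Direction-tuning model for a simulated neuron
#'
#' Firing rate is `baseline_rate` during the blank and, during the grating,
#' `baseline + (peak - baseline) * g(dir - preferred) *
#' (1 + modulation_depth * sin(2 * pi * f_t * t))`, clipped at zero, where
#' `g` is a von Mises-shaped gain normalized to 1 at the preferred
#' direction and `f_t` the grating temporal frequency. Untuned cells
#' (`is_tuned = FALSE`) fire at `baseline_rate` throughout.
#'
#' @param preferred_direction Degrees in [0, 360).
#' @param tuning_width von Mises concentration parameter (dimensionless);
#'   larger is narrower tuning.
#' @param baseline_rate Spontaneous rate, spikes/s.
#' @param peak_rate Rate at the preferred direction (before sinusoidal
#'   modulation), spikes/s; must be `>= baseline_rate`.
#' @param modulation_depth Fractional amplitude in [0, 1] of the sinusoidal
#'   rate modulation at the grating temporal frequency.
#' @param is_tuned Logical; `FALSE` gives a baseline-only (null) cell.
#' @return An object of class `tuning_model`.
#' @export
tuning_model <- function(preferred_direction = 0, tuning_width = 4,
                         baseline_rate = 1, peak_rate = 20,
                         modulation_depth = 0.6, is_tuned = TRUE) {
  if (baseline_rate < 0) stop("baseline_rate must be >= 0", call. = FALSE)
  if (peak_rate < baseline_rate)
    stop("peak_rate must be >= baseline_rate", call. = FALSE)
  if (modulation_depth < 0 || modulation_depth > 1)
    stop("modulation_depth must be in [0, 1]", call. = FALSE)
  if (preferred_direction < 0 || preferred_direction >= 360)
    stop("preferred_direction must be in [0, 360)", call. = FALSE)
  structure(list(
    preferred_direction = preferred_direction,
    tuning_width = tuning_width,
    baseline_rate = baseline_rate,
    peak_rate = peak_rate,
    modulation_depth = modulation_depth,
    is_tuned = isTRUE(is_tuned)
  ), class = "tuning_model")
}

#' von Mises-shaped direction gain
#'
#' `exp(kappa * (cos(theta - pref) - 1))`: equals 1 at the preferred
#' direction and decays symmetrically with angular distance.
#'
#' @param direction_deg Stimulus direction(s), degrees.
#' @param preferred_deg Preferred direction, degrees.
#' @param kappa Concentration parameter.
#' @return Gain in (0, 1].
#' @export
direction_gain <- function(direction_deg, preferred_deg, kappa) {
  exp(kappa * (cos((direction_deg - preferred_deg) * pi / 180) - 1))
}

#' Imaging scene model
#'
#' Geometry, population size, contamination and noise of a simulated
#' two-photon field of view. Defaults match the standard acquisition:
#' 512 x 512 pixels spanning 250 x 250 um^2 of layer-2/3 cortex.
#'
#' @param field_of_view Side of the square field of view, um.
#' @param image_size Side of the square image, pixels.
#' @param n_cells Number of somata in the scene.
#' @param soma_radius Soma radius, um.
#' @param nucleus_radius Nucleus radius, um; must be `< soma_radius`.
#'   Somatic rings exclude the nucleus, where cytosolic indicator is absent.
#' @param neuropil_amplitude Neuropil baseline brightness as a fraction of
#'   mean soma baseline brightness.
#' @param contamination_ratio_true True additive contamination ratio of the
#'   neuropil signal into measured somatic traces, in [0, 1].
#' @param noise_sd_frac Gaussian measurement noise SD as a fraction of soma
#'   baseline fluorescence (per frame).
#' @param noise_model `"gaussian"` (additive, SD `noise_sd_frac * baseline`)
#'   or `"photon"` (Poisson-like: SD scales with the square root of the
#'   signal, calibrated so a pixel at baseline has the same SD as the
#'   gaussian model).
#' @return An object of class `scene_model`.
#' @export
scene_model <- function(field_of_view = 250, image_size = 512, n_cells = 30,
                        soma_radius = 6, nucleus_radius = 3,
                        neuropil_amplitude = 0.8,
                        contamination_ratio_true = 0.7,
                        noise_sd_frac = 0.05,
                        noise_model = c("gaussian", "photon")) {
  noise_model <- match.arg(noise_model)
  if (nucleus_radius >= soma_radius)
    stop("nucleus_radius must be smaller than soma_radius", call. = FALSE)
  if (contamination_ratio_true < 0 || contamination_ratio_true > 1)
    stop("contamination_ratio_true must be in [0, 1]", call. = FALSE)
  if (noise_sd_frac < 0) stop("noise_sd_frac must be >= 0", call. = FALSE)
  structure(list(
    field_of_view = field_of_view,
    image_size = as.integer(image_size),
    n_cells = as.integer(n_cells),
    soma_radius = soma_radius,
    nucleus_radius = nucleus_radius,
    neuropil_amplitude = neuropil_amplitude,
    contamination_ratio_true = contamination_ratio_true,
    noise_sd_frac = noise_sd_frac,
    noise_model = noise_model
  ), class = "scene_model")
}

#' @export
print.scene_model <- function(x, ...) {
  cat(sprintf(
    "scene_model: %d cells, %d px spanning %g um (%.3f um/px), r_true = %g\n",
    x$n_cells, x$image_size, x$field_of_view,
    x$field_of_view / x$image_size, x$contamination_ratio_true))
  invisible(x)
}
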