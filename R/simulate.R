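#' Unitary fluorescence kernel for an indicator
#'
#' The per-spike transient is a difference of exponentials,
#' `k(t) = exp(-t / tau_d) - exp(-t / tau_r)` for `t >= 0`, peak-normalized
#' to 1. `tau_r` is the model's `rise_time`; `tau_d` is solved numerically
#' (one-dimensional root finding) so that the time for the kernel to fall
#' from its peak to half its peak equals `decay_half_time` exactly.
#'
#' @param kinetics A [kinetics_model()].
#' @return A list with `tau_r`, `tau_d`, `t_peak` (seconds), `support`
#'   (time beyond which the kernel is negligible) and `fn`, a vectorized
#'   function of time since spike returning the peak-normalized kernel.
#' @export
fluorescence_kernel <- function(kinetics) {
  tau_r <- kinetics$rise_time
  target <- kinetics$decay_half_time

  peak_time <- function(tau_d) {
    tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  }
  raw <- function(t, tau_d) exp(-t / tau_d) - exp(-t / tau_r)
  half_decay_of <- function(tau_d) {
    tp <- peak_time(tau_d)
    fp <- raw(tp, tau_d)
    th <- stats::uniroot(function(t) raw(t, tau_d) - fp / 2,
                         lower = tp, upper = tp + 20 * tau_d,
                         tol = 1e-12)$root
    th - tp
  }
  ## half-decay grows monotonically with tau_d; bracket and solve
  lo <- tau_r * 1.0001
  hi <- max(2 * target / log(2), 4 * tau_r)
  while (half_decay_of(hi) < target) hi <- hi * 2
  tau_d <- stats::uniroot(function(x) half_decay_of(x) - target,
                          lower = lo, upper = hi, tol = 1e-12)$root
  tp <- peak_time(tau_d)
  peak <- raw(tp, tau_d)
  list(
    tau_r = tau_r, tau_d = tau_d, t_peak = tp,
    support = tp + tau_d * log(1e5),
    fn = function(t) ifelse(t >= 0, (exp(-t / tau_d) - exp(-t / tau_r)) / peak, 0)
  )
}

## Instantaneous firing rate (spikes/s) at absolute session times `t`.
rate_function <- function(tuning, protocol) {
  tt <- trial_table(protocol)
  trial_dur <- protocol$blank_duration + protocol$stim_duration
  force(tuning)
  function(t) {
    r <- rep(tuning$baseline_rate, length(t))
    if (!tuning$is_tuned || tuning$peak_rate == tuning$baseline_rate)
      return(r)
    trial <- pmin(floor(t / trial_dur) + 1, nrow(tt))
    within <- t - tt$blank_start[trial]
    in_stim <- within >= protocol$blank_duration & t < tt$stim_end[trial]
    if (any(in_stim)) {
      ts <- within[in_stim] - protocol$blank_duration
      gain <- direction_gain(tt$direction_deg[trial[in_stim]],
                             tuning$preferred_direction, tuning$tuning_width)
      mod <- 1 + tuning$modulation_depth *
        sin(2 * pi * protocol$temporal_frequency * ts)
      r[in_stim] <- tuning$baseline_rate +
        (tuning$peak_rate - tuning$baseline_rate) * gain * mod
    }
    pmax(r, 0)
  }
}

#' Simulate a spike train under the grating protocol
#'
#' Draws an inhomogeneous Poisson spike train over one full session by
#' thinning: the rate is `baseline_rate` during blanks and a
#' direction-tuned, sinusoidally modulated rate during gratings (see
#' [tuning_model()]).
#'
#' @param tuning A [tuning_model()].
#' @param protocol A [stimulus_protocol()].
#' @param seed Optional integer seed; when given, the draw is reproducible.
#' @return An object of class `spike_train`: a list with `times` (sorted
#'   absolute spike times, seconds), `trial` (trial index per spike) and
#'   `protocol`.
#' @export
generate_spike_trains <- function(tuning, protocol, seed = NULL) {
  if (!inherits(protocol, "stimulus_protocol"))
    stop("invalid protocol", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rate <- rate_function(tuning, protocol)
  total_t <- n_trials_total(protocol) *
    (protocol$blank_duration + protocol$stim_duration)
  rate_max <- if (tuning$is_tuned)
    tuning$baseline_rate + (tuning$peak_rate - tuning$baseline_rate) *
      (1 + tuning$modulation_depth)
  else tuning$baseline_rate
  if (rate_max <= 0) {
    times <- numeric(0)
  } else {
    n <- stats::rpois(1, rate_max * total_t)
    cand <- sort(stats::runif(n, 0, total_t))
    keep <- stats::runif(n) < rate(cand) / rate_max
    times <- cand[keep]
  }
  trial_dur <- protocol$blank_duration + protocol$stim_duration
  structure(list(
    times = times,
    trial = if (length(times)) pmin(floor(times / trial_dur) + 1L,
                                    n_trials_total(protocol)) else integer(0),
    protocol = protocol
  ), class = "spike_train")
}

#' Spike times split by trial
#' @param spikes A `spike_train` from [generate_spike_trains()].
#' @return A list of length `n_trials_total(protocol)`; element i holds the
#'   spike times of trial i relative to that trial's start (seconds).
#' @export
spikes_by_trial <- function(spikes) {
  protocol <- spikes$protocol
  nt <- n_trials_total(protocol)
  trial_dur <- protocol$blank_duration + protocol$stim_duration
  out <- vector("list", nt)
  for (i in seq_len(nt)) {
    sel <- spikes$trial == i
    out[[i]] <- spikes$times[sel] - (i - 1) * trial_dur
  }
  out
}

#' Convert spikes to a cytosolic fluorescence trace
#'
#' The cytosolic fluorescence sampled at the imaging frame grid is
#' `F(t) = B * (1 + a * sum_i k(t - t_i))`: baseline `B` plus a linear
#' superposition of peak-normalized unitary kernels scaled by the per-spike
#' dF/F amplitude `a`. Transients sum linearly and carry across trial
#' boundaries, as in a continuously recorded session.
#'
#' @param spikes A `spike_train` or a numeric vector of absolute spike
#'   times (seconds).
#' @param kinetics A [kinetics_model()].
#' @param protocol A [stimulus_protocol()].
#' @return Numeric vector, one fluorescence value (arbitrary units) per
#'   frame of the session.
#' @export
spikes_to_fluorescence <- function(spikes, kinetics, protocol) {
  if (inherits(spikes, "spike_train")) spikes <- spikes$times
  t <- frame_times(protocol)
  kern <- fluorescence_kernel(kinetics)
  dff <- numeric(length(t))
  fr <- protocol$frame_rate
  for (ts in spikes) {
    i0 <- max(1L, ceiling(ts * fr) + 1L)  # first frame with t >= ts
    i1 <- min(length(t), floor((ts + kern$support) * fr) + 1L)
    if (i0 > i1) next
    idx <- i0:i1
    dff[idx] <- dff[idx] + kern$fn(t[idx] - ts)
  }
  kinetics$baseline_fluorescence *
    (1 + kinetics$amplitude_per_spike * dff)
}

#' Build a neuropil trace coupled to population activity
#'
#' The neuropil is modeled as a spatial average of surrounding processes:
#' its baseline is `neuropil_amplitude` times the mean somatic baseline, and
#' it fluctuates with the population-average dF/F (scaled by `coupling`),
#' so that contamination is correlated with signal, as the subtraction
#' correction assumes.
#'
#' @param cyto Matrix of cytosolic traces, cells x frames.
#' @param baselines Per-cell baseline fluorescence (arbitrary units).
#' @param scene A [scene_model()].
#' @param coupling Fraction of the population-mean dF/F transferred to the
#'   neuropil trace.
#' @return Numeric vector, one value per frame.
#' @export
make_neuropil_trace <- function(cyto, baselines, scene, coupling = 0.5) {
  stopifnot(nrow(cyto) == length(baselines))
  pop_dff <- colMeans(sweep(sweep(cyto, 1, baselines, "-"), 1, baselines, "/"))
  scene$neuropil_amplitude * mean(baselines) * (1 + coupling * pop_dff)
}

#' Compose measured traces from cytosolic signal and neuropil
#'
#' The measured somatic trace is the forward measurement model that the
#' subtraction correction inverts:
#' `F_measured(t) = F_cyto(t) + r_true * F_neuropil(t) + noise`.
#' A neuropil-ROI measurement of the neuropil trace is returned alongside
#' (with reduced noise, reflecting its larger pixel count).
#'
#' @param cyto Matrix of cytosolic traces, cells x frames.
#' @param neuropil Numeric neuropil trace, one value per frame.
#' @param scene A [scene_model()]; supplies `contamination_ratio_true` and
#'   the noise model.
#' @param baselines Per-cell baseline fluorescence used to scale noise;
#'   defaults to per-cell trace medians.
#' @param seed Optional integer seed for the noise draw.
#' @return A list with `measured` (cells x frames matrix) and
#'   `neuropil_measured` (vector).
#' @export
compose_measurement <- function(cyto, neuropil, scene,
                                baselines = apply(cyto, 1, stats::median),
                                seed = NULL) {
  if (ncol(cyto) != length(neuropil))
    stop("cytosolic traces and neuropil trace must share the frame grid",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  r <- scene$contamination_ratio_true
  measured <- sweep(cyto, 2, r * neuropil, "+")
  if (scene$noise_sd_frac > 0) {
    if (scene$noise_model == "gaussian") {
      sd_mat <- matrix(scene$noise_sd_frac * baselines,
                       nrow(cyto), ncol(cyto))
    } else {
      sd_mat <- scene$noise_sd_frac *
        sqrt(pmax(measured, 0) * baselines)
    }
    measured <- measured + stats::rnorm(length(measured)) * sd_mat
    np_sd <- scene$noise_sd_frac * mean(baselines) / 5
    neuropil_meas <- neuropil + stats::rnorm(length(neuropil), sd = np_sd)
  } else {
    neuropil_meas <- neuropil
  }
  list(measured = measured, neuropil_measured = neuropil_meas)
}

#' Simulate a population imaging session with ground truth
#'
#' Draws tuning parameters, spike trains, cytosolic traces, a
#' population-coupled neuropil trace, and measured (contaminated, noisy)
#' traces for `n_cells` neurons under the grating protocol. A designed
#' fraction of cells is direction tuned; the rest fire at baseline only.
#'
#' @param n_cells Number of cells.
#' @param protocol A [stimulus_protocol()].
#' @param scene A [scene_model()].
#' @param indicator `"fast"` or `"slow"` preset, or a [kinetics_model()].
#' @param tuned_fraction Fraction of cells that are direction tuned.
#' @param tuning_args Named list of overrides passed to [tuning_model()]
#'   for tuned cells (e.g. `peak_rate`, `modulation_depth`).
#' @param baseline_cv Coefficient of variation of per-cell baseline
#'   fluorescence (log-normal across cells).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return An object of class `sim_population`: list with `protocol`,
#'   `scene`, `kinetics`, `measured` (cells x frames), `neuropil_measured`,
#'   and `ground_truth` (spike trains, tuning models, per-cell baselines,
#'   cytosolic traces, noiseless neuropil trace, true contamination ratio).
#' @export
simulate_population <- function(n_cells, protocol = stimulus_protocol(),
                                scene = scene_model(n_cells = n_cells),
                                indicator = "fast", tuned_fraction = 1,
                                tuning_args = list(), baseline_cv = 0.2,
                                seed = 1) {
  set.seed(seed)
  kin0 <- if (inherits(indicator, "kinetics_model")) indicator
          else indicator_preset(indicator)
  n_tuned <- round(n_cells * tuned_fraction)
  is_tuned <- seq_len(n_cells) <= n_tuned
  prefs <- stats::runif(n_cells, 0, 360)
  tunings <- lapply(seq_len(n_cells), function(i) {
    args <- utils::modifyList(
      list(preferred_direction = prefs[i], is_tuned = is_tuned[i]),
      tuning_args)
    do.call(tuning_model, args)
  })
  sdlog <- sqrt(log(1 + baseline_cv^2))
  baselines <- kin0$baseline_fluorescence *
    stats::rlnorm(n_cells, -sdlog^2 / 2, sdlog)

  nf <- n_frames_total(protocol)
  cyto <- matrix(0, n_cells, nf)
  spike_trains <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    kin_i <- kin0
    kin_i$baseline_fluorescence <- baselines[i]
    spike_trains[[i]] <- generate_spike_trains(tunings[[i]], protocol)
    cyto[i, ] <- spikes_to_fluorescence(spike_trains[[i]], kin_i, protocol)
  }
  neuropil <- make_neuropil_trace(cyto, baselines, scene)
  meas <- compose_measurement(cyto, neuropil, scene, baselines = baselines)
  structure(list(
    protocol = protocol, scene = scene, kinetics = kin0,
    measured = meas$measured, neuropil_measured = meas$neuropil_measured,
    ground_truth = list(
      spike_trains = spike_trains, tuning = tunings,
      baselines = baselines, cyto = cyto, neuropil = neuropil,
      contamination_ratio_true = scene$contamination_ratio_true,
      is_tuned = is_tuned
    )
  ), class = "sim_population")
}
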