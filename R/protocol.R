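#' Drifting-grating stimulus protocol
#'
#' Describes the timing and geometry of a blank/grating trial-based visual
#' stimulation experiment: each trial is a uniform-gray blank period followed
#' by a drifting sinusoidal grating in one of `n_directions` equally spaced
#' directions. Defaults reproduce the standard V1 population-imaging
#' protocol: 4 s blank, 4 s grating at 1 Hz temporal frequency and
#' 0.05 cycles/degree, 8 directions, 15 Hz frame rate, 5 trials per
#' direction.
#'
#' @param blank_duration Blank (gray screen) duration per trial, seconds.
#' @param stim_duration Grating duration per trial, seconds.
#' @param n_directions Number of equally spaced drift directions.
#' @param temporal_frequency Grating temporal frequency, Hz.
#' @param spatial_frequency Grating spatial frequency, cycles/degree
#'   (metadata only; no spatial receptive fields are modeled).
#' @param frame_rate Imaging frame rate, Hz. `frame_rate *
#'   (blank_duration + stim_duration)` must be a whole number of frames.
#' @param n_trials_per_direction Trials presented per direction.
#' @return An object of class `stimulus_protocol`.
#' @examples
#' p <- stimulus_protocol()
#' n_frames_per_trial(p)  # 120
#' @export
stimulus_protocol <- function(blank_duration = 4, stim_duration = 4,
                              n_directions = 8, temporal_frequency = 1,
                              spatial_frequency = 0.05, frame_rate = 15,
                              n_trials_per_direction = 5) {
  if (blank_duration <= 0 || stim_duration <= 0)
    stop("protocol durations must be positive", call. = FALSE)
  if (n_directions < 1 || n_directions != round(n_directions))
    stop("n_directions must be a positive integer", call. = FALSE)
  if (frame_rate <= 0)
    stop("frame_rate must be positive", call. = FALSE)
  if (n_trials_per_direction < 1)
    stop("n_trials_per_direction must be >= 1", call. = FALSE)
  fpt <- frame_rate * (blank_duration + stim_duration)
  if (abs(fpt - round(fpt)) > 1e-9)
    stop("frame_rate * trial duration must be an integer frame count",
         call. = FALSE)
  structure(list(
    blank_duration = blank_duration,
    stim_duration = stim_duration,
    n_directions = as.integer(n_directions),
    temporal_frequency = temporal_frequency,
    spatial_frequency = spatial_frequency,
    frame_rate = frame_rate,
    n_trials_per_direction = as.integer(n_trials_per_direction)
  ), class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "stimulus_protocol: %g s blank + %g s grating, %d directions x %d trials\n",
    x$blank_duration, x$stim_duration, x$n_directions,
    x$n_trials_per_direction))
  cat(sprintf("  temporal freq %g Hz, spatial freq %g cpd, frame rate %g Hz\n",
              x$temporal_frequency, x$spatial_frequency, x$frame_rate))
  invisible(x)
}

#' Frames per trial and per session
#' @param protocol A [stimulus_protocol()].
#' @return Integer frame count.
#' @export
n_frames_per_trial <- function(protocol) {
  as.integer(round(protocol$frame_rate *
                     (protocol$blank_duration + protocol$stim_duration)))
}

#' @rdname n_frames_per_trial
#' @export
n_frames_total <- function(protocol) {
  n_frames_per_trial(protocol) * n_trials_total(protocol)
}

#' @rdname n_frames_per_trial
#' @export
n_trials_total <- function(protocol) {
  protocol$n_directions * protocol$n_trials_per_direction
}

#' Stimulus directions in degrees
#' @param protocol A [stimulus_protocol()].
#' @return Numeric vector of length `n_directions`, degrees in [0, 360).
#' @export
protocol_directions <- function(protocol) {
  (seq_len(protocol$n_directions) - 1) * 360 / protocol$n_directions
}

#' Session trial table
#'
#' Lays the trials of one session end-to-end on a common time axis, cycling
#' through the directions `n_trials_per_direction` times. Times are seconds
#' from session start; frame k (1-based) starts at `(k - 1) / frame_rate`.
#'
#' @param protocol A [stimulus_protocol()].
#' @return A data frame with columns `trial`, `direction_index` (1-based),
#'   `direction_deg`, `blank_start`, `stim_start`, `stim_end` (seconds).
#' @export
trial_table <- function(protocol) {
  nt <- n_trials_total(protocol)
  dir_idx <- rep(seq_len(protocol$n_directions),
                 times = protocol$n_trials_per_direction)
  trial_dur <- protocol$blank_duration + protocol$stim_duration
  blank_start <- (seq_len(nt) - 1) * trial_dur
  data.frame(
    trial = seq_len(nt),
    direction_index = dir_idx,
    direction_deg = protocol_directions(protocol)[dir_idx],
    blank_start = blank_start,
    stim_start = blank_start + protocol$blank_duration,
    stim_end = blank_start + trial_dur
  )
}

#' Frame start times for a session
#' @param protocol A [stimulus_protocol()].
#' @return Numeric vector, seconds; frame k starts at `(k - 1) / frame_rate`.
#' @export
frame_times <- function(protocol) {
  (seq_len(n_frames_total(protocol)) - 1) / protocol$frame_rate
}

## Frame-index helpers. All windows are half-open in frame *start* time:
## a frame belongs to [a, b) when a <= t_start < b.
frames_in_window <- function(protocol, from, to) {
  t <- frame_times(protocol)
  which(t >= from - 1e-9 & t < to - 1e-9)
}

#' Frame indices of a trial's stimulus or blank period
#' @param protocol A [stimulus_protocol()].
#' @param trial Trial number (1-based).
#' @param period `"stim"` or `"blank"`.
#' @return Integer vector of frame indices into the session trace.
#' @export
trial_frames <- function(protocol, trial, period = c("stim", "blank")) {
  period <- match.arg(period)
  tt <- trial_table(protocol)
  if (trial < 1 || trial > nrow(tt))
    stop("trial out of range", call. = FALSE)
  row <- tt[trial, ]
  if (period == "stim")
    frames_in_window(protocol, row$stim_start, row$stim_end)
  else
    frames_in_window(protocol, row$blank_start, row$stim_start)
}

#' Pre-stimulus baseline frame indices of a trial
#'
#' Frames whose start times fall in the half-open window
#' `[stim_start - window_s, stim_start)` immediately before grating onset,
#' used for F0 estimation and kinetics baselines.
#'
#' @param protocol A [stimulus_protocol()].
#' @param trial Trial number (1-based).
#' @param window_s Baseline window length, seconds (see
#'   [baseline_window_s()]).
#' @return Integer vector of frame indices.
#' @export
baseline_frames <- function(protocol, trial, window_s) {
  tt <- trial_table(protocol)
  row <- tt[trial, ]
  if (window_s > protocol$blank_duration + 1e-9)
    stop("baseline window exceeds blank duration", call. = FALSE)
  frames_in_window(protocol, row$stim_start - window_s, row$stim_start)
}

#' Baseline-window length for an indicator class
#'
#' F0 (and kinetics baseline statistics) are averaged over a 2 s pre-stimulus
#' window for fast indicators (GCaMP6f-class) and a 1 s window for slow
#' indicators (GCaMP6s-class).
#'
#' @param indicator `"fast"` or `"slow"`.
#' @return Window length in seconds.
#' @export
baseline_window_s <- function(indicator = c("fast", "slow")) {
  indicator <- match.arg(indicator)
  if (indicator == "fast") 2 else 1
}
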